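# Peak-centric pan-cell example sampling and the training loop with
# dice-based model selection.

#' CellTypeData: one training cell type's paired data
#'
#' Pairs a min-max-normalized accessibility track with the ATAC peak calls
#' and the ChIP-seq TFBS (peaks) of the modeled TF for one cell type; the
#' optional ChIP signal track (-log10 p-value) feeds the averaged-ChIP
#' baseline.
#'
#' @slot name Cell-type name.
#' @slot atacTrack \code{SignalTrack}, min-max normalized.
#' @slot atacPeaks \code{GRanges} of accessible-chromatin peaks.
#' @slot chipPeaks \code{GRanges} of ChIP-seq TFBS for the modeled TF.
#' @slot chipSignal Optional \code{SignalTrack} of ChIP -log10 p-values
#'   (NULL allowed).
#' @export
setClass("CellTypeData",
  representation(name = "character", atacTrack = "SignalTrack",
                 atacPeaks = "GRanges", chipPeaks = "GRanges",
                 chipSignal = "ANY"),
  prototype(chipSignal = NULL))

setValidity("CellTypeData", function(object) {
  if (normalizationState(object@atacTrack) != "minmax")
    return("atacTrack must be minmax-normalized")
  TRUE
})

#' @rdname CellTypeData-class
#' @param name,atacTrack,atacPeaks,chipPeaks,chipSignal See slots.
#' @export
cellTypeData <- function(name, atacTrack, atacPeaks, chipPeaks,
                         chipSignal = NULL) {
  new("CellTypeData", name = name, atacTrack = atacTrack,
      atacPeaks = atacPeaks, chipPeaks = chipPeaks, chipSignal = chipSignal)
}

setMethod("show", "CellTypeData", function(object) {
  cat("CellTypeData", object@name, ":", length(object@atacPeaks),
      "ATAC peaks,", length(object@chipPeaks), "ChIP peaks\n")
})

#' Train/validation/test chromosome split
#'
#' The default reserves chr2 and chr19 for validation and chr1 and chr8 for
#' testing, with the remaining listed autosomes for training, so that DNA
#' sequence never leaks between partitions.
#'
#' @param train,validation,test Character vectors of chromosome names
#'   (pairwise disjoint).
#' @return A list of class \code{"ChromosomeSplit"}.
#' @export
chromosomeSplit <- function(
    train = paste0("chr", c(3:7, 9:11, 13:18, 20)),
    validation = c("chr2", "chr19"),
    test = c("chr1", "chr8")) {
  if (length(intersect(train, validation)) || length(intersect(train, test)) ||
      length(intersect(validation, test)))
    stop("train/validation/test chromosome sets must be pairwise disjoint")
  structure(list(train = train, validation = validation, test = test),
            class = "ChromosomeSplit")
}

#' Bin-level binding labels for a window
#'
#' The window is split into \code{bins} equal bins; a bin is labeled
#' positive iff its total bp overlap with the ChIP peaks strictly exceeds
#' half the bin width (for 32 bp bins: 17 bp or more).
#'
#' @param chipPeaks ChIP-seq TFBS \code{GRanges}.
#' @param window A single window \code{GRanges} (length divisible by
#'   \code{bins}).
#' @param bins Number of label bins (default 32).
#' @return Integer vector of \code{bins} 0/1 labels.
#' @export
makeLabels <- function(chipPeaks, window, bins = 32L) {
  stopifnot(length(window) == 1L, width(window) %% bins == 0L)
  bw <- width(window) %/% bins
  starts <- start(window) + (seq_len(bins) - 1L) * bw
  b <- GRanges(seqnames(window), IRanges(starts, width = bw))
  pk <- reduce(chipPeaks[as.character(seqnames(chipPeaks)) ==
                           as.character(seqnames(window))],
               ignore.strand = TRUE)
  ov <- findOverlaps(b, pk, ignore.strand = TRUE)
  inter <- pintersect(b[S4Vectors::queryHits(ov)], pk[S4Vectors::subjectHits(ov)])
  bp <- tapply(width(inter), S4Vectors::queryHits(ov), sum)
  lab <- integer(bins)
  if (length(bp))
    lab[as.integer(names(bp))] <- as.integer(bp > bw / 2)
  lab
}

#' Build the region-of-interest pool
#'
#' The union of accessible chromatin (ATAC peaks) and TFBS (ChIP peaks)
#' across training cell types, restricted to the given partition's
#' chromosomes, blacklist-overlapping entries removed, each interval tagged
#' with its origin cell type and class.
#'
#' @param cellTypes List of \linkS4class{CellTypeData}.
#' @param split A [chromosomeSplit()].
#' @param partition \code{"train"} or \code{"validation"}.
#' @param blacklist Optional blacklist \code{GRanges}.
#' @return A \code{GRanges} with metadata columns \code{origin_cell} and
#'   \code{origin_class} (\code{"ATAC"}/\code{"ChIP"}).
#' @export
buildRoiPool <- function(cellTypes, split,
                         partition = c("train", "validation"),
                         blacklist = NULL) {
  partition <- match.arg(partition)
  chroms <- split[[partition]]
  pieces <- lapply(cellTypes, function(ct) {
    tag <- function(gr, cls) {
      gr <- gr[as.character(seqnames(gr)) %in% chroms]
      mcols(gr) <- S4Vectors::DataFrame(
        origin_cell = rep(ct@name, length(gr)),
        origin_class = rep(cls, length(gr)))
      gr
    }
    c(tag(ct@atacPeaks, "ATAC"), tag(ct@chipPeaks, "ChIP"))
  })
  pool <- suppressWarnings(do.call(c, unname(pieces)))
  pool <- applyBlacklist(pool, blacklist)
  if (length(pool) == 0L)
    stop("empty region-of-interest pool for partition '", partition,
         "': no peaks on its chromosomes; regenerate the fixture or check ",
         "the chromosome split")
  pool
}

#' Training-loop configuration
#'
#' Defaults reproduce the published training routine (ADAM, learning rate
#' 0.001, 100 epochs of 100 batches of 1,000 examples, fully peak-centric
#' pan-cell sampling, reverse-complement augmentation off). Toy fixtures
#' use reduced budgets.
#'
#' @param learning_rate ADAM learning rate.
#' @param epochs,batch_size,batches_per_epoch Budget counts.
#' @param random_ratio Fraction of examples sampled uniformly from the
#'   training chromosomes (0 = fully peak-centric).
#' @param pan_cell Draw the signal/label cell type uniformly across
#'   training cell types, independent of an interval's origin.
#' @param rc_augment Double each batch with reverse complements.
#' @param val_examples Validation examples drawn (once) for dice-based
#'   epoch selection.
#' @param seed Integer seed; all training randomness flows from it.
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learning_rate = 0.001, epochs = 100L,
                        batch_size = 1000L, batches_per_epoch = 100L,
                        random_ratio = 0, pan_cell = TRUE,
                        rc_augment = FALSE, val_examples = 512L, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, batches_per_epoch >= 1L,
            random_ratio >= 0, random_ratio <= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 random_ratio = random_ratio, pan_cell = isTRUE(pan_cell),
                 rc_augment = isTRUE(rc_augment),
                 val_examples = as.integer(val_examples),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# ASCII code -> one-hot channel (A=1 C=2 G=3 T=4, case-insensitive; other
# letters, e.g. N, stay NA and encode as all-zero).
.dnaCode <- local({
  x <- rep(NA_integer_, 127L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("a")] <- 1L
  x[utf8ToInt("C")] <- 2L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("g")] <- 3L
  x[utf8ToInt("T")] <- 4L; x[utf8ToInt("t")] <- 4L
  x
})

#' One-hot encode a DNA sequence
#'
#' @param s Character scalar or \code{DNAString}.
#' @return A length x 4 matrix (columns A, C, G, T); ambiguous bases are
#'   all-zero rows.
#' @export
oneHotDNA <- function(s) {
  v <- utf8ToInt(as.character(s))
  m <- matrix(0, length(v), 4L)
  idx <- .dnaCode[v]
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

# Dense numeric signal for a 1-based closed window on one chromosome.
windowSignal <- function(track, chrom, start, end) {
  as.numeric(S4Vectors::window(trackSignal(track)[[chrom]], start, end))
}

# Precomputed dense per-chromosome views used by the example sampler:
# chromosome sequence as character, per-cell signal vectors, cumulative
# ChIP-peak base indicators (for O(1) bin-overlap counts) and a cumulative
# blacklist indicator. Decoding is per (cell type, chromosome) and is only
# intended for the listed chromosomes.
samplerContext <- function(cellTypes, genome, chroms, blacklist = NULL) {
  si <- seqinfo(cellTypes[[1L]]@atacTrack)
  sl <- seqlengths(si)
  chroms <- intersect(chroms, names(sl))
  seqs <- setNames(lapply(chroms, function(chr)
    as.character(genome[[chr]])), chroms)
  sig <- lapply(cellTypes, function(ct)
    setNames(lapply(chroms, function(chr)
      as.numeric(trackSignal(ct@atacTrack)[[chr]])), chroms))
  chipCum <- lapply(cellTypes, function(ct) {
    cov <- coverage(reduce(ct@chipPeaks, ignore.strand = TRUE),
                    width = as.list(sl))
    setNames(lapply(chroms, function(chr)
      c(0, cumsum(as.integer(cov[[chr]] > 0L)))), chroms)
  })
  blCum <- if (is.null(blacklist) || !length(blacklist)) NULL else {
    cov <- coverage(reduce(blacklist, ignore.strand = TRUE),
                    width = as.list(sl))
    setNames(lapply(chroms, function(chr)
      c(0, cumsum(as.integer(cov[[chr]] > 0L)))), chroms)
  }
  list(sl = sl, seqs = seqs, sig = sig, chipCum = chipCum, blCum = blCum)
}

# Resolve a centered window of length L inside [1, chromLen], shifting to
# fit; returns c(start, end) or NULL when the chromosome is shorter than L.
fitWindow <- function(mid, L, chromLen) {
  if (chromLen < L) return(NULL)
  st <- mid - L %/% 2L + 1L
  st <- max(1L, min(st, chromLen - L + 1L))
  c(st, st + L - 1L)
}

#' Sample training examples
#'
#' Draws n windows of the model's input length: a fraction
#' \code{random_ratio} uniformly from the partition chromosomes and the
#' rest centered on uniformly drawn region-of-interest pool intervals.
#' Under pan-cell sampling the cell type supplying both signal and labels
#' is drawn uniformly from all cell types, independent of the interval's
#' origin; otherwise it is the interval's origin cell type. Labels always
#' describe binding in the cell type whose accessibility is shown.
#'
#' @param pool \code{GRanges} from [buildRoiPool()].
#' @param cellTypes Named list of \linkS4class{CellTypeData} (names =
#'   cell-type names).
#' @param genome A \code{DNAStringSet} of chromosome sequences.
#' @param chroms Chromosomes eligible for uniform (random-ratio) windows.
#' @param config A [trainConfig()] (fields \code{random_ratio},
#'   \code{pan_cell}).
#' @param n Number of examples.
#' @param inputLength,bins Window length and label bins (default 1024/32).
#' @param blacklist Optional blacklist; uniform windows overlapping it are
#'   redrawn.
#' @param context Optional precomputed sampler context (internal; built
#'   automatically when NULL). [trainModel()] builds it once and reuses it
#'   across batches.
#' @return List with \code{X} (inputLength x 5 x n array), \code{labels}
#'   (bins x n matrix), \code{cellType} (character n), \code{windows}
#'   (\code{GRanges}).
#' @export
sampleExamples <- function(pool, cellTypes, genome, chroms, config, n,
                           inputLength = 1024L, bins = 32L,
                           blacklist = NULL, context = NULL) {
  stopifnot(n >= 1L, inputLength %% bins == 0L)
  if (is.null(names(cellTypes)))
    names(cellTypes) <- vapply(cellTypes, function(ct) ct@name, character(1))
  si <- seqinfo(cellTypes[[1L]]@atacTrack)
  if (is.null(context))
    context <- samplerContext(cellTypes, genome,
                              union(chroms,
                                    unique(as.character(seqnames(pool)))),
                              blacklist)
  sl <- context$sl
  chroms <- intersect(chroms, names(sl)[sl >= inputLength])
  bw <- inputLength %/% bins
  isRandom <- runif(n) < config$random_ratio
  X <- array(0, dim = c(inputLength, 5L, n))
  labels <- matrix(0L, bins, n)
  cellType <- character(n)
  wChrom <- character(n)
  wStart <- integer(n)
  ctNames <- names(cellTypes)
  poolChrom <- as.character(seqnames(pool))
  poolMid <- (start(pool) + end(pool)) %/% 2L
  poolOrigin <- pool$origin_cell
  binOffsets <- (0:bins) * bw
  for (i in seq_len(n)) {
    if (isRandom[i]) {
      repeat {
        chr <- chroms[sample.int(length(chroms), 1L, prob = sl[chroms])]
        st <- sample.int(sl[[chr]] - inputLength + 1L, 1L)
        bl <- context$blCum[[chr]]
        if (is.null(bl) ||
            bl[st + inputLength] - bl[st] == 0) break
      }
      origin <- NA_character_
    } else {
      j <- sample.int(length(poolChrom), 1L)
      chr <- poolChrom[j]
      se <- fitWindow(poolMid[j], inputLength, sl[[chr]])
      if (is.null(se))
        stop("chromosome ", chr, " shorter than the input window")
      st <- se[1L]
      origin <- poolOrigin[j]
    }
    ct <- if (config$pan_cell || is.na(origin))
      ctNames[sample.int(length(ctNames), 1L)] else origin
    en <- st + inputLength - 1L
    v <- utf8ToInt(substr(context$seqs[[chr]], st, en))
    idx <- .dnaCode[v]
    ok <- which(!is.na(idx))
    X[cbind(ok, idx[ok], i)] <- 1
    X[, 5L, i] <- context$sig[[ct]][[chr]][st:en]
    cumc <- context$chipCum[[ct]][[chr]]
    cnt <- diff(cumc[st + binOffsets])
    labels[, i] <- as.integer(cnt > bw / 2)
    cellType[i] <- ct
    wChrom[i] <- chr
    wStart[i] <- st
  }
  windows <- GRanges(wChrom, IRanges(wStart, width = inputLength),
                     seqinfo = si)
  list(X = X, labels = labels, cellType = cellType, windows = windows,
       random = isRandom)
}

#' Reverse-complement a training example
#'
#' One-hot channels are complement-swapped (A<->T, C<->G) and
#' position-reversed; signal and labels are reversed. An involution:
#' applying it twice restores the example.
#'
#' @param example List with \code{X} (L x 5 matrix or L x 5 x n array) and
#'   \code{labels} (vector or bins x n matrix); extra fields pass through.
#' @return The reverse-complemented example(s).
#' @export
reverseComplementAugment <- function(example) {
  rc1 <- function(m) {
    out <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    out[, 1:4] <- out[, c(4L, 3L, 2L, 1L)]
    out
  }
  if (length(dim(example$X)) == 3L) {
    for (i in seq_len(dim(example$X)[3L]))
      example$X[, , i] <- rc1(example$X[, , i])
    example$labels <- example$labels[rev(seq_len(nrow(example$labels))), ,
                                     drop = FALSE]
  } else {
    example$X <- rc1(example$X)
    example$labels <- rev(example$labels)
  }
  example
}

#' Train a model
#'
#' Optimizes mean binary cross-entropy with ADAM over peak-centric
#' pan-cell batches, evaluating the soft dice coefficient on a fixed
#' validation-example set (validation chromosomes) after every epoch and
#' returning the parameters of the epoch with maximal validation dice.
#' All randomness flows from \code{config$seed}; a fixed seed reproduces
#' the history exactly.
#'
#' @param model An untrained (or warm) \linkS4class{ModelHandle}.
#' @param cellTypes Named list of \linkS4class{CellTypeData}.
#' @param genome A \code{DNAStringSet}.
#' @param split A [chromosomeSplit()].
#' @param config A [trainConfig()].
#' @param blacklist Optional blacklist \code{GRanges}.
#' @return A trained \code{ModelHandle}; \code{trainingHistory()} holds
#'   one row per epoch (epoch, loss, val_dice, val_aupr).
#' @export
trainModel <- function(model, cellTypes, genome, split, config,
                       blacklist = NULL) {
  if (is.null(names(cellTypes)))
    names(cellTypes) <- vapply(cellTypes, function(ct) ct@name, character(1))
  spec <- model@spec
  trainPool <- buildRoiPool(cellTypes, split, "train", blacklist)
  valPool <- buildRoiPool(cellTypes, split, "validation", blacklist)
  trainCtx <- samplerContext(cellTypes, genome, split$train, blacklist)
  valCtx <- samplerContext(cellTypes, genome, split$validation, blacklist)
  withSeed(config$seed, {
    val <- sampleExamples(valPool, cellTypes, genome, split$validation,
                          config, config$val_examples,
                          inputLength = spec@inputLength,
                          bins = spec@outputBins, blacklist = blacklist,
                          context = valCtx)
    session <- nn_session_new(model@params)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          val_dice = numeric(), val_aupr = numeric())
    bestDice <- -Inf
    bestParams <- model@params
    for (epoch in seq_len(config$epochs)) {
      epochLoss <- 0
      for (batch in seq_len(config$batches_per_epoch)) {
        ex <- sampleExamples(trainPool, cellTypes, genome, split$train,
                             config, config$batch_size,
                             inputLength = spec@inputLength,
                             bins = spec@outputBins, blacklist = blacklist,
                             context = trainCtx)
        if (config$rc_augment) {
          rc <- reverseComplementAugment(ex)
          ex$X <- array(c(ex$X, rc$X),
                        dim = c(dim(ex$X)[1:2], 2L * dim(ex$X)[3L]))
          ex$labels <- cbind(ex$labels, rc$labels)
        }
        loss <- nn_session_train_batch(session, ex$X, ex$labels,
                                       config$learning_rate)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", epoch,
               ", batch ", batch,
               " (exploding gradients; reduce the learning rate)")
        epochLoss <- epochLoss + loss
      }
      params <- nn_session_params(session)
      valProb <- nnForward(params, val$X, training = FALSE)$prob
      vd <- diceCoefficient(valProb, val$labels)
      va <- if (sum(val$labels) > 0) {
        auprc(prCurve(data.frame(score = as.numeric(valProb),
                                 label = as.integer(val$labels))))
      } else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epochLoss / config$batches_per_epoch,
        val_dice = vd, val_aupr = va))
      if (vd > bestDice) {
        bestDice <- vd
        bestParams <- params
      }
    }
    new("ModelHandle", spec = spec, params = bestParams, seed = model@seed,
        trained = TRUE, history = history)
  })
}
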