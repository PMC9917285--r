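# Genome-tiled prediction (optionally on variant-substituted donor
# sequence), score-to-performance calibration, and thresholded BED output.

#' Substitute variants into a reference sequence
#'
#' Applies homozygous-alternate single-nucleotide substitutions to the
#' reference, producing a donor-specific sequence of unchanged length.
#'
#' @param sequence A named \code{DNAStringSet} (reference chromosomes).
#' @param variants A \code{data.frame} with columns \code{chrom},
#'   \code{pos} (0-based), \code{ref}, \code{alt} and optionally
#'   \code{genotype} (must be \code{"hom-alt"} when present).
#' @return The personalized \code{DNAStringSet}.
#' @export
applyVariants <- function(sequence, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(sequence)
  if (!is.null(variants$genotype) && any(variants$genotype != "hom-alt"))
    stop("only homozygous-alternate variants are supported; phase or drop ",
         "heterozygous calls first")
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("indels are unsupported: only single-nucleotide substitutions")
  for (chr in unique(variants$chrom)) {
    v <- variants[variants$chrom == chr, , drop = FALSE]
    if (!chr %in% names(sequence))
      stop("variant chromosome ", chr, " absent from the sequence set")
    at <- v$pos + 1L  # 0-based -> 1-based
    have <- as.character(Biostrings::extractAt(sequence[[chr]],
                                               IRanges(at, at)))
    bad <- which(have != v$ref)
    if (length(bad))
      stop("reference allele mismatch at ", chr, ":", v$pos[bad[1L]],
           " (0-based): expected ", v$ref[bad[1L]], ", found ",
           have[bad[1L]])
    sequence[[chr]] <- replaceLetterAt(sequence[[chr]], at,
                                       paste(v$alt, collapse = ""))
  }
  sequence
}

#' Genome-tiled TFBS prediction
#'
#' Tiles each chromosome into non-overlapping windows of the model's input
#' length from position 0, pads the trailing partial window with N
#' sequence (all-zero one-hot) and zero signal, discards predictions
#' beyond the chromosome end, and zeroes bins overlapping the blacklist.
#'
#' @param model A trained \linkS4class{ModelHandle}.
#' @param genome A named \code{DNAStringSet}.
#' @param signalTrack A min-max-normalized \code{SignalTrack}.
#' @param chroms Chromosomes to predict (default: all in the track).
#' @param blacklist Optional blacklist \code{GRanges}.
#' @param batchSize Windows per forward pass (default 256).
#' @return A \linkS4class{PredictionTrack} at the model's output-bin
#'   resolution (one score per ceiling(length / bin) bin per chromosome).
#' @export
predictGenome <- function(model, genome, signalTrack, chroms = NULL,
                          blacklist = NULL, batchSize = 256L) {
  spec <- model@spec
  L <- spec@inputLength
  binW <- L %/% spec@outputBins
  si <- seqinfo(signalTrack)
  if (is.null(chroms)) chroms <- names(seqlengths(si))
  if (normalizationState(signalTrack) != "minmax" ||
      any(vapply(trackSignal(signalTrack)[chroms], function(r)
        if (length(r)) max(runValue(r)) > 1 + 1e-9 else FALSE, logical(1))))
    stop("signal track is not min-max normalized to [0,1]; run ",
         "minmaxNormalize() first")
  sl <- seqlengths(si)[chroms]
  si2 <- Seqinfo(chroms, unname(sl))
  out <- setNames(vector("list", length(chroms)), chroms)
  for (chr in chroms) {
    len <- sl[[chr]]
    nWin <- ceiling(len / L)
    nBins <- ceiling(len / binW)
    scores <- numeric(nWin * spec@outputBins)
    starts <- (seq_len(nWin) - 1L) * L + 1L
    for (b0 in seq(1L, nWin, by = batchSize)) {
      idx <- b0:min(nWin, b0 + batchSize - 1L)
      X <- array(0, dim = c(L, 5L, length(idx)))
      for (k in seq_along(idx)) {
        st <- starts[idx[k]]
        en <- min(st + L - 1L, len)
        avail <- en - st + 1L
        X[seq_len(avail), 1:4, k] <- oneHotDNA(subseq(genome[[chr]], st, en))
        X[seq_len(avail), 5L, k] <- windowSignal(signalTrack, chr, st, en)
      }
      prob <- predictWindows(model, X)
      scores[(idx[1L] - 1L) * spec@outputBins +
               seq_len(length(idx) * spec@outputBins)] <- as.numeric(prob)
    }
    scores <- scores[seq_len(nBins)]
    if (!is.null(blacklist) && length(blacklist)) {
      binGr <- GRanges(chr, IRanges((seq_len(nBins) - 1L) * binW + 1L,
                                    width = binW))
      scores[overlapsAny(binGr, blacklist, ignore.strand = TRUE)] <- 0
    }
    r <- Rle(rep(scores, each = binW))
    out[[chr]] <- S4Vectors::window(r, 1L, len)  # truncate trailing bin
  }
  new("PredictionTrack",
      signal = RleList(out, compress = FALSE), seqinfo = si2,
      normalization = "other", minmaxParams = list(), binWidth = binW)
}

#' Map scores to validation performance
#'
#' Sweeps a fixed threshold grid over the prediction track, computing
#' precision, recall, F1 and log2(precision / random precision) against a
#' gold standard via the 200 bp-bin procedure, then reduces the table to a
#' one-to-one score-to-precision mapping: thresholds are scanned in
#' ascending order and a row is kept only when its precision strictly
#' exceeds every smaller threshold's, so a precision value attained at
#' several thresholds keeps the threshold of maximal recall.
#'
#' @param prediction_track A \linkS4class{PredictionTrack}.
#' @param gold ChIP-seq gold-standard \code{GRanges} (validation
#'   chromosomes).
#' @param blacklist Optional blacklist \code{GRanges}.
#' @param grid_step Score-grid step (default 0.001).
#' @param bin_width Evaluation bin width in bp (default 200).
#' @param chroms Optional chromosome subset.
#' @return A \code{data.frame} with columns \code{threshold},
#'   \code{precision}, \code{recall}, \code{F1},
#'   \code{log2_precision_over_random}; precision strictly increasing and
#'   recall non-increasing with threshold.
#' @export
calibrate <- function(prediction_track, gold, blacklist = NULL,
                      grid_step = 0.001, bin_width = 200L, chroms = NULL) {
  if (is.null(gold) || length(gold) == 0L)
    stop("empty gold standard: calibration requires validation ChIP peaks")
  ev <- binnedEvaluation(prediction_track, gold, blacklist, bin_width, chroms)
  ev <- ev[!ev$excluded, , drop = FALSE]
  npos <- sum(ev$label)
  if (npos == 0L)
    stop("gold standard does not overlap any evaluated bin")
  prand <- npos / nrow(ev)
  sAll <- sort(ev$score)
  sPos <- sort(ev$score[ev$label == 1L])
  thresholds <- seq(0, 1, by = grid_step)
  nPred <- length(sAll) - findInterval(thresholds, sAll, left.open = TRUE)
  tp <- length(sPos) - findInterval(thresholds, sPos, left.open = TRUE)
  keepRows <- nPred > 0L
  thresholds <- thresholds[keepRows]
  precision <- tp[keepRows] / nPred[keepRows]
  recall <- tp[keepRows] / npos
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  keep <- logical(length(thresholds))
  best <- -Inf
  for (i in seq_along(thresholds)) {
    if (precision[i] > best) {
      keep[i] <- TRUE
      best <- precision[i]
    }
  }
  data.frame(threshold = thresholds[keep], precision = precision[keep],
             recall = recall[keep], F1 = f1[keep],
             log2_precision_over_random =
               log2FoldChange(precision[keep], prand))[order(thresholds[keep]), ]
}

#' Threshold predictions into a BED-ready interval set
#'
#' Maximal runs of consecutive bins with score >= cutoff are merged into
#' single intervals carrying the run's maximum score.
#'
#' @param prediction_track A \linkS4class{PredictionTrack}.
#' @param cutoff Score cutoff in [0,1] (e.g. a threshold chosen from
#'   [calibrate()] by target F1 or precision).
#' @return A \code{GRanges} of predicted TFBS with metadata column
#'   \code{score}.
#' @export
thresholdToBed <- function(prediction_track, cutoff) {
  stopifnot(cutoff >= 0)
  sig <- trackSignal(prediction_track)
  si <- seqinfo(prediction_track)
  pieces <- lapply(names(sig), function(chr) {
    v <- IRanges::slice(sig[[chr]], lower = cutoff, includeLower = TRUE)
    if (!length(v)) return(GRanges(seqinfo = si))
    GRanges(chr, IRanges(start(v), end(v)), score = viewMaxs(v),
            seqinfo = si)
  })
  do.call(c, pieces)
}
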