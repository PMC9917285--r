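# Precision-recall machinery at fixed-width genomic bins, plus the two
# baselines: PWM motif-count ranking and arcsinh-averaged training ChIP
# signal.

#' Maximum score per fixed-width bin
#'
#' Tiles each chromosome into non-overlapping bins of \code{bin_width} bp
#' from position 0 and reports the maximum per-base score overlapping each
#' bin; a trailing partial bin is dropped so the bin width stays constant.
#'
#' @param track A \code{SignalTrack} or \code{PredictionTrack}.
#' @param bin_width Bin width in bp (default 200).
#' @param chroms Optional subset of chromosomes.
#' @return A \code{GRanges} of bins with metadata column \code{score}.
#' @export
binScores <- function(track, bin_width = 200L, chroms = NULL) {
  stopifnot(bin_width > 0L)
  sig <- trackSignal(track)
  si <- seqinfo(track)
  if (is.null(chroms)) chroms <- names(sig)
  pieces <- lapply(chroms, function(chr) {
    r <- sig[[chr]]
    nb <- length(r) %/% bin_width
    if (nb == 0L) return(GRanges(seqinfo = si))
    v <- Views(r, successiveIRanges(rep(bin_width, nb)))
    GRanges(chr, IRanges(start = (seq_len(nb) - 1L) * bin_width + 1L,
                         width = bin_width),
            score = viewMaxs(v), seqinfo = si)
  })
  do.call(c, pieces)
}

#' Gold-standard labels for bins
#'
#' A bin is labeled positive iff it overlaps a ChIP-seq peak by at least
#' 1 bp (contrast with the training-label rule, which requires >50%
#' overlap of a 32 bp bin).
#'
#' @param bins A \code{GRanges} of bins.
#' @param chipPeaks ChIP-seq peak \code{GRanges}.
#' @return Integer 0/1 labels, one per bin.
#' @export
labelBins <- function(bins, chipPeaks) {
  as.integer(overlapsAny(bins, chipPeaks, ignore.strand = TRUE))
}

#' Assemble a binned evaluation table
#'
#' Bins a score track, attaches gold-standard labels and flags bins
#' overlapping the blacklist as excluded; excluded bins never enter the
#' precision-recall computation (neither numerators nor denominators).
#'
#' @param track Score \code{SignalTrack}/\code{PredictionTrack}.
#' @param gold ChIP-seq gold-standard peak \code{GRanges}.
#' @param blacklist Optional blacklist \code{GRanges}.
#' @param bin_width Bin width in bp (default 200).
#' @param chroms Optional chromosome subset (e.g. the test chromosomes).
#' @return A \code{data.frame} with columns \code{chrom}, \code{start}
#'   (0-based), \code{score}, \code{label}, \code{excluded}.
#' @export
binnedEvaluation <- function(track, gold, blacklist = NULL, bin_width = 200L,
                             chroms = NULL) {
  bins <- binScores(track, bin_width, chroms)
  data.frame(chrom = as.character(seqnames(bins)), start = start(bins) - 1L,
             score = bins$score, label = labelBins(bins, gold),
             excluded = if (is.null(blacklist)) FALSE else
               overlapsAny(bins, blacklist, ignore.strand = TRUE))
}

#' Precision-recall curve over ranked bins
#'
#' Thresholds at each unique score, descending; tied scores enter
#' together. At each threshold, precision is the fraction of
#' predicted-positive bins (score >= threshold) overlapping the gold
#' standard, and recall the fraction of gold-standard bins recovered.
#' Excluded bins are removed first.
#'
#' @param bins A \code{data.frame} with columns \code{score} and
#'   \code{label} (and optionally \code{excluded}).
#' @return A \code{data.frame} with columns \code{threshold},
#'   \code{n_pred}, \code{tp}, \code{precision}, \code{recall}, one row
#'   per unique threshold (descending).
#' @export
prCurve <- function(bins) {
  if (!is.null(bins$excluded)) bins <- bins[!bins$excluded, , drop = FALSE]
  npos <- sum(bins$label)
  if (npos == 0L)
    stop("no positive bins among non-excluded bins: precision-recall is undefined")
  ord <- order(bins$score, decreasing = TRUE)
  score <- bins$score[ord]
  label <- bins$label[ord]
  cumTp <- cumsum(label)
  n <- length(score)
  # last index of each tie group (the final group always closes at n)
  last <- c(which(score[-n] != score[-1L]), n)
  data.frame(threshold = score[last], n_pred = last, tp = cumTp[last],
             precision = cumTp[last] / last, recall = cumTp[last] / npos)
}

#' Area under the precision-recall curve
#'
#' Average-precision step sum over descending thresholds:
#' \code{sum_i (R_i - R_[i-1]) * P_i}.
#'
#' @param curve Output of [prCurve()].
#' @return AUPR in [0,1].
#' @export
auprc <- function(curve) {
  r <- c(0, curve$recall)
  sum(diff(r) * curve$precision)
}

#' Precision at a fixed recall
#'
#' The precision at the first threshold (descending) whose recall reaches
#' \code{r}.
#'
#' @param curve Output of [prCurve()].
#' @param r Target recall (default 0.05).
#' @return Precision at \code{r} recall.
#' @export
precisionAtRecall <- function(curve, r = 0.05) {
  i <- which(curve$recall >= r)
  if (!length(i))
    stop("recall ", r, " is never reached by the ranking")
  curve$precision[i[1L]]
}

#' Random (baseline) precision
#'
#' The positive-bin fraction: gold-standard bins divided by all
#' non-excluded bins. Equals the expected precision of a uniformly random
#' ranking and the asymptotic AUPR of random scores.
#'
#' @param bins A \code{data.frame} as for [prCurve()].
#' @return Numeric in [0,1].
#' @export
randomPrecision <- function(bins) {
  if (!is.null(bins$excluded)) bins <- bins[!bins$excluded, , drop = FALSE]
  if (nrow(bins) == 0L) stop("no non-excluded bins")
  sum(bins$label) / nrow(bins)
}

#' Pseudocounted log2 fold change
#'
#' \code{log2((a + pseudocount) / (b + pseudocount))}; the pseudocount
#' (default 0.1) moderates high fold changes between small performance
#' values.
#'
#' @param a,b Non-negative values (e.g. AUPRs of two methods).
#' @param pseudocount Added to both (default 0.1).
#' @return The log2 ratio.
#' @export
log2FoldChange <- function(a, b, pseudocount = 0.1) {
  stopifnot(all(a >= 0), all(b >= 0))
  log2((a + pseudocount) / (b + pseudocount))
}

#' Read PWMs from MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME minimal motif file
#' into \linkS4class{Pwm} objects.
#'
#' @param path Path to the MEME file.
#' @param pseudocount Regularization pseudocount per matrix cell.
#' @return A named list of \code{Pwm}.
#' @export
readMeme <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF entries in ", path)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- grep("^letter-probability matrix", lines[(s + 1L):length(lines)])[1L]
    if (is.na(h)) stop("motif ", id, " lacks a letter-probability matrix")
    h <- s + h
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(f) as.numeric(f[1:4]), numeric(4)))
    pwms[[id]] <- Pwm(t(m), id = id, pseudocount = pseudocount)
  }
  pwms
}

# Integer-discretized log-odds scoring matrix and the exact distribution of
# the score under the background model (i.i.d. background across motif
# positions), by dynamic programming over the discretized score range.
pwmScoreDistribution <- function(pwm, granularity = 1e-3) {
  lo <- log2(pwm@matrix / pwm@background)
  sc <- round(lo / granularity)  # integer scores, 4 x w
  w <- ncol(sc)
  colmin <- apply(sc, 2, min)
  sc0 <- sweep(sc, 2, colmin)  # per-column zero-floored scores
  lob <- sum(colmin)
  # p[i] = P(zero-floored partial score == i - 1); true score = lob + i - 1
  # at the end. Zero-flooring keeps every prefix index in range.
  p <- numeric(sum(apply(sc0, 2, max)) + 1L)
  for (b in 1:4)
    p[sc0[b, 1L] + 1L] <- p[sc0[b, 1L] + 1L] + pwm@background[b]
  for (j in seq_len(w)[-1L]) {
    q <- numeric(length(p))
    nz <- which(p > 0)
    for (b in 1:4) {
      sh <- sc0[b, j]
      q[nz + sh] <- q[nz + sh] + p[nz] * pwm@background[b]
    }
    p <- q
  }
  list(scores = sc, offset = lob, probs = p, granularity = granularity)
}

#' Log-odds score threshold for a p-value
#'
#' Exact dynamic programming over the discretized score distribution under
#' the background model: the smallest integer score s with
#' \code{P(score >= s) <= p_threshold}.
#'
#' @param pwm A \linkS4class{Pwm}.
#' @param p_threshold Match p-value threshold (default 1e-5).
#' @param granularity Score discretization (default 1e-3 log2 units).
#' @return Integer threshold on the discretized score scale, with the
#'   distribution attached as attribute \code{"distribution"}; \code{Inf}
#'   when no attainable score is that rare.
#' @export
pwmScoreThreshold <- function(pwm, p_threshold = 1e-5, granularity = 1e-3) {
  d <- pwmScoreDistribution(pwm, granularity)
  surv <- rev(cumsum(rev(d$probs)))  # P(score >= s) for s = offset + i - 1
  ok <- which(surv <= p_threshold)
  thr <- if (length(ok)) d$offset + ok[1L] - 1L else Inf
  structure(thr, distribution = d)
}

#' Scan sequences for motif occurrences
#'
#' Scores every position of every sequence (both strands) with the
#' discretized log-odds matrix and reports matches whose p-value under the
#' background model is below \code{p_threshold}. Exact-coordinate
#' duplicate hits (e.g. a palindromic site matched on both strands) are
#' removed; overlapping non-identical matches are retained.
#'
#' @param sequences A named \code{DNAStringSet}. Names of the form
#'   \code{"chrom:start-end"} (1-based closed, as produced by extracting
#'   peak sequences) map hits back to genomic coordinates; otherwise the
#'   name is used as the chromosome and hits are sequence-local.
#' @param pwm A \linkS4class{Pwm}.
#' @param p_threshold Match p-value threshold (default 1e-5).
#' @param granularity Score discretization (default 1e-3).
#' @return A \code{GRanges} of motif hits with metadata column
#'   \code{motif_id}; strand records the matched orientation.
#' @export
pwmScan <- function(sequences, pwm, p_threshold = 1e-5, granularity = 1e-3) {
  thr <- pwmScoreThreshold(pwm, p_threshold, granularity)
  w <- ncol(pwm@matrix)
  hits <- list()
  if (is.finite(thr)) {
    sc <- attr(thr, "distribution")$scores
    rcsc <- sc[4:1, w:1, drop = FALSE]  # reverse-complement strand matrix
    nms <- names(sequences)
    if (is.null(nms)) nms <- paste0("seq", seq_along(sequences))
    loc <- regmatches(nms, regexec("^(.*):(\\d+)-(\\d+)$", nms))
    for (i in seq_along(sequences)) {
      s <- as.character(sequences[[i]])
      n <- nchar(s)
      if (n < w) next
      code <- .dnaCode[utf8ToInt(s)]
      if (anyNA(code)) code[is.na(code)] <- 0L
      npos <- n - w + 1L
      fwd <- numeric(npos)
      rev_ <- numeric(npos)
      valid <- rep(TRUE, npos)
      for (j in seq_len(w)) {
        cj <- code[j:(j + npos - 1L)]
        bad <- cj == 0L
        valid <- valid & !bad
        cj[bad] <- 1L
        fwd <- fwd + sc[cbind(cj, j)]
        rev_ <- rev_ + rcsc[cbind(cj, j)]
      }
      if (length(loc[[i]]) == 4L) {
        chrom <- loc[[i]][2L]
        off <- as.integer(loc[[i]][3L]) - 1L
      } else {
        chrom <- nms[i]
        off <- 0L
      }
      fi <- which(valid & fwd >= thr)
      ri <- which(valid & rev_ >= thr)
      if (length(fi))
        hits[[length(hits) + 1L]] <- data.frame(chrom = chrom,
                                                start = off + fi,
                                                strand = "+")
      if (length(ri))
        hits[[length(hits) + 1L]] <- data.frame(chrom = chrom,
                                                start = off + ri,
                                                strand = "-")
    }
  }
  if (!length(hits))
    return(GRanges(motif_id = character(0)))
  df <- do.call(rbind, hits)
  out <- sort(GRanges(df$chrom, IRanges(df$start, width = w),
                      strand = df$strand, motif_id = pwm@id),
              ignore.strand = TRUE)
  out[!duplicated(paste(seqnames(out), start(out), end(out)))]
}

#' Motif-count ranking scores per bin
#'
#' Counts the motif hits overlapping each bin by at least 1 bp; the counts
#' are the ranking scores fed to [prCurve()] for the motif-scanning
#' baseline.
#'
#' @param hits Motif hit \code{GRanges} from [pwmScan()] (multiple motifs'
#'   hits may be concatenated).
#' @param bins A bin \code{GRanges} (see [binScores()]) or a
#'   \code{data.frame} from [binnedEvaluation()] is not accepted here;
#'   pass the \code{GRanges}.
#' @return Integer hit counts, one per bin.
#' @export
motifRankBins <- function(hits, bins) {
  countOverlaps(bins, hits, minoverlap = 1L, ignore.strand = TRUE)
}

#' Averaged-ChIP baseline track
#'
#' Averages arcsinh-transformed ChIP-seq signal (-log10 p-value) across
#' training cell types at each genomic position; the result is ranked via
#' [binScores()] and [prCurve()] as a simple non-ATAC baseline.
#'
#' @param chip_signal_tracks List of \code{SignalTrack}s over identical
#'   chromosomes.
#' @return A \code{SignalTrack} of per-base mean arcsinh signal.
#' @export
averageChipBaseline <- function(chip_signal_tracks) {
  stopifnot(length(chip_signal_tracks) >= 1L)
  si <- seqinfo(chip_signal_tracks[[1L]])
  for (t in chip_signal_tracks[-1L])
    if (!identical(seqlengths(seqinfo(t)), seqlengths(si)))
      stop("ChIP signal tracks have mismatched chromosome sets")
  tr <- lapply(chip_signal_tracks, function(t)
    RleList(lapply(trackSignal(t), function(r) {
      runValue(r) <- asinh(runValue(r))
      r
    }), compress = FALSE))
  SignalTrack(Reduce(`+`, tr) / length(tr), si, normalization = "other")
}
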