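# Shared oracles and small fixtures. Every oracle here recomputes its
# quantity from first principles (loops / enumeration), independent of the
# package's vectorized implementations.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
  library(GenomicRanges)
  library(GenomeInfoDb)
})

tinySeqinfo <- function(lengths = c(chrT = 1000L)) {
  GenomeInfoDb::Seqinfo(names(lengths), unname(lengths))
}

trackFromVectors <- function(vectors, normalization = "raw") {
  si <- tinySeqinfo(vapply(vectors, length, integer(1)))
  SignalTrack(vectors, si, normalization = normalization)
}

denseTrack <- function(track, chrom) {
  as.numeric(S4Vectors::decode(trackSignal(track)[[chrom]]))
}

# Eq-by-eq brute-force precision/recall/random precision at one threshold:
# predicted-positive bins are those with score >= threshold.
brutePRAt <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  list(precision = if (sum(pred)) tp / sum(pred) else NA_real_,
       recall = tp / sum(labels == 1L))
}

# Average-precision step sum by exhaustive threshold enumeration.
bruteAUPR <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0
  ap <- 0
  for (t in thr) {
    pr <- brutePRAt(scores, labels, t)
    ap <- ap + (pr$recall - prevR) * pr$precision
    prevR <- pr$recall
  }
  ap
}

# Nearest-rank percentile of a multiset given by values and multiplicities.
bruteNearestRank <- function(values, mult, p) {
  expanded <- rep(values, mult)
  sorted <- sort(expanded)
  sorted[ceiling(p / 100 * length(sorted))]
}

# Double-precision reference of the fused same-padded dilated conv (+ReLU).
refConv <- function(X, W, b, d, relu = FALSE) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  L <- dim(X)[1]; B <- dim(X)[3]; cen <- (k - 1) %/% 2
  Y <- array(0, c(L, Cout, B))
  for (s in seq_len(B)) for (o in seq_len(Cout)) {
    acc <- rep(b[o], L)
    for (t in seq_len(k)) for (c in seq_len(Cin)) {
      off <- (t - 1 - cen) * d
      src <- seq_len(L) + off
      ok <- src >= 1 & src <= L
      acc[ok] <- acc[ok] + X[src[ok], c, s] * W[t, c, o]
    }
    if (relu) acc <- pmax(acc, 0)
    Y[, o, s] <- acc
  }
  Y
}

# A generated fixture plus prepared cell types, cached per seed so several
# test files can share the same toy study.
.fixtureCache <- new.env(parent = emptyenv())
getFixture <- function(seed = 11L) {
  key <- as.character(seed)
  if (is.null(.fixtureCache[[key]])) {
    truth <- generateFixture(fixtureConfig(seed = seed))
    .fixtureCache[[key]] <- list(truth = truth,
                                 cells = prepareFixtureCellTypes(truth))
  }
  .fixtureCache[[key]]
}

# Tiny architecture used where only shape/dispatch is under test.
tinySpec <- function(inputLength = 64L, outputBins = 16L, nBlocks = 2L,
                     kernelWidth = 3L, baseFilters = 4L,
                     dilationSchedule = c(1L, 2L, 4L)) {
  architectureSpec(inputLength = inputLength, inputChannels = 5L,
                   nBlocks = nBlocks, layersPerBlock = 2L,
                   kernelWidth = kernelWidth, baseFilters = baseFilters,
                   filterGrowth = 1.5, dilationSchedule = dilationSchedule,
                   poolWidth = 2L, outputBins = outputBins)
}
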