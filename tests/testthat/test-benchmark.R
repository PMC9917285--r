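test_that("bin scores are the per-bin maximum with trailing remainder dropped", {
  tr <- trackFromVectors(list(chrT = rep(0.3, 450)))
  bins <- binScores(tr, 200L)
  expect_length(bins, 2L)  # 450bp -> two full 200bp bins
  expect_equal(bins$score, c(0.3, 0.3))
  spike <- numeric(450); spike[333] <- 0.9
  b2 <- binScores(trackFromVectors(list(chrT = spike)), 200L)
  expect_equal(b2$score, c(0, 0.9))
  set.seed(14)
  v <- runif(1000)
  b3 <- binScores(trackFromVectors(list(chrT = v)), 200L)
  expect_equal(b3$score, apply(matrix(v, nrow = 200), 2, max))
})

test_that("gold labels use any-overlap (>=1bp) semantics", {
  bins <- GRanges("chrT", IRanges(c(1, 201, 401), width = 200))
  expect_equal(labelBins(bins, GRanges("chrT", IRanges(200, 250))),
               c(1L, 1L, 0L))
  # adjacent but non-overlapping in half-open coordinates: 0-based [200,400)
  # does not touch [400,600)
  expect_equal(labelBins(bins, GRanges("chrT", IRanges(201, 400))),
               c(0L, 1L, 0L))
  expect_equal(sum(labelBins(bins, GRanges("chrT", IRanges(150, 450)))), 3L)
})

test_that("precision-recall follows the ranked-bin definitions", {
  bins <- data.frame(score = c(0.9, 0.8, 0.7, 0.6), label = c(1L, 0L, 1L, 0L))
  cur <- prCurve(bins)
  expect_equal(cur$threshold, c(0.9, 0.8, 0.7, 0.6))
  last <- nrow(cur)
  expect_equal(cur$precision[last], 0.5)
  expect_equal(cur$recall[last], 1.0)
  expect_equal(auprc(cur), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect ranking
  perf <- prCurve(data.frame(score = c(3, 2, 1), label = c(1L, 1L, 0L)))
  expect_equal(auprc(perf), 1.0)
  expect_true(any(perf$precision == 1 & perf$recall == 1))
  # ties enter together
  tied <- prCurve(data.frame(score = c(0.5, 0.5), label = c(1L, 0L)))
  expect_equal(nrow(tied), 1L)
  expect_equal(tied$precision, 0.5)
  expect_error(prCurve(data.frame(score = 1, label = 0L)), "no positive")
})

test_that("precision at fixed recall reads the first crossing", {
  cur <- prCurve(data.frame(score = c(0.9, 0.8, 0.7, 0.6),
                            label = c(1L, 0L, 1L, 0L)))
  expect_equal(precisionAtRecall(cur, 0.05), 1.0)
  expect_equal(precisionAtRecall(cur, 0.75), 2 / 3)
  expect_error(precisionAtRecall(cur, 1.5), "never reached")
})

test_that("random precision is the positive fraction of non-excluded bins", {
  bins <- data.frame(score = runif(100), label = rep(c(1L, 0L), c(5, 95)))
  expect_equal(randomPrecision(bins), 0.05)
  expect_equal(randomPrecision(data.frame(score = 1:3, label = rep(1L, 3))), 1)
  withEx <- data.frame(score = runif(10), label = rep(c(1L, 0L), 5),
                       excluded = rep(c(TRUE, FALSE), c(2, 8)))
  kept <- withEx[!withEx$excluded, ]
  expect_equal(randomPrecision(withEx), sum(kept$label) / nrow(kept))
})

test_that("pr machinery matches brute-force recomputation on random instances", {
  set.seed(100)
  for (i in 1:30) {
    n <- sample(20:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force some ties
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1L
    bins <- data.frame(score = scores, label = labels)
    cur <- prCurve(bins)
    for (t in cur$threshold) {
      ref <- brutePRAt(scores, labels, t)
      row <- cur[cur$threshold == t, ]
      expect_equal(row$precision, ref$precision, tolerance = 1e-9)
      expect_equal(row$recall, ref$recall, tolerance = 1e-9)
    }
    expect_equal(auprc(cur), bruteAUPR(scores, labels), tolerance = 1e-9)
  }
})

test_that("log2 fold change applies the 0.1 pseudocount", {
  expect_equal(log2FoldChange(0.4, 0.4), 0)
  expect_equal(log2FoldChange(0.3, 0.1), 1)
  expect_equal(log2FoldChange(0, 0), 0)
  expect_error(log2FoldChange(-1, 0))
})

consensusMeme <- function(path, probs = 0.997) {
  # TGCA consensus, near-deterministic columns
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "",
             "MOTIF TGCA_consensus",
             "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
             " 0.001 0.001 0.001 0.997",
             " 0.001 0.001 0.997 0.001",
             " 0.001 0.997 0.001 0.001",
             " 0.997 0.001 0.001 0.001")
  writeLines(lines, path)
  path
}

test_that("MEME minimal parsing yields normalized PWMs", {
  path <- withr::local_tempfile(fileext = ".meme")
  consensusMeme(path)
  pwms <- readMeme(path)
  expect_length(pwms, 1L)
  pwm <- pwms[[1]]
  expect_s4_class(pwm, "Pwm")
  expect_equal(ncol(pwm@matrix), 4L)
  expect_equal(colSums(pwm@matrix), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(pwm@matrix["T", 1]), 0.997, tolerance = 1e-3)
})

test_that("p-value thresholding matches exhaustive 4-mer enumeration", {
  path <- withr::local_tempfile(fileext = ".meme")
  consensusMeme(path)
  pwm <- readMeme(path)[[1]]
  # enumerate all 256 4-mers under the uniform background
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                 collapse = "")
  loInt <- round(log2(pwm@matrix / pwm@background) / 1e-3)
  kint <- vapply(kmers, function(km) {
    idx <- match(strsplit(km, "")[[1]], bases)
    sum(loInt[cbind(idx, 1:4)])
  }, numeric(1))
  empSurv <- vapply(kint, function(s) mean(kint >= s), numeric(1))
  # p = 1e-2: exactly the k-mers whose enumerated p-value is within the
  # threshold pass (here: the consensus only, p = 1/256)
  thr2 <- pwmScoreThreshold(pwm, 1e-2)
  expect_true(is.finite(thr2))
  expect_equal(kint >= thr2, empSurv <= 1e-2)
  expect_equal(kmers[kint >= thr2], "TGCA")
  # p = 1e-5: even the consensus (p = 1/256) is too common -> no threshold
  expect_false(is.finite(pwmScoreThreshold(pwm, 1e-5)))
})

test_that("motif scanning hits consensus occurrences on both strands only", {
  path <- withr::local_tempfile(fileext = ".meme")
  consensusMeme(path)
  pwm <- readMeme(path)[[1]]
  # TGCA is its own reverse complement, so both strands match at one locus
  seqs <- Biostrings::DNAStringSet(c("chrM:101-140" =
    "AAAAAATGCAAAAAAAAAAAAAAAAAAAATGCAAAAAAAA"))
  hits <- pwmScan(seqs, pwm, p_threshold = 1e-2)
  expect_equal(sort(unique(start(hits) - 1L)), c(106L, 129L))  # 0-based genomic
  expect_equal(width(hits), rep(4L, length(hits)))
  # exact-coordinate duplicates (palindrome matched on both strands) removed
  expect_equal(length(hits), 2L)
  expect_length(pwmScan(seqs, pwm, p_threshold = 1e-5), 0L)
  # a uniform PWM scores 0 everywhere: no hits at any p < 1
  flat <- Pwm(matrix(0.25, 4, 4), id = "flat")
  expect_length(pwmScan(seqs, flat, p_threshold = 0.5), 0L)
})

test_that("motif counts per bin use any-overlap and feed pr ranking", {
  bins <- GRanges("chrM", IRanges(c(1, 201), width = 200))
  hits <- GRanges("chrM", IRanges(c(10, 50, 195), width = 8))
  counts <- motifRankBins(hits, bins)
  expect_equal(counts, c(3L, 1L))  # the straddling hit counts in both bins
  expect_equal(motifRankBins(GRanges(), bins), c(0L, 0L))
})

test_that("the averaged-ChIP baseline is the mean arcsinh signal", {
  expect_equal(asinh(0), 0)
  t1 <- trackFromVectors(list(chrT = c(0, 1, 4)), normalization = "other")
  single <- averageChipBaseline(list(t1))
  expect_equal(denseTrack(single, "chrT"), asinh(c(0, 1, 4)))
  expect_equal(denseTrack(single, "chrT")[2], log(1 + sqrt(2)))
  t2 <- trackFromVectors(list(chrT = c(2, 2, 2)), normalization = "other")
  avg <- averageChipBaseline(list(t1, t2))
  expect_equal(denseTrack(avg, "chrT"), (asinh(c(0, 1, 4)) + asinh(2)) / 2)
  bad <- trackFromVectors(list(other = 1), normalization = "other")
  expect_error(averageChipBaseline(list(t1, bad)), "mismatched")
})
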