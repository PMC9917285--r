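si1k <- tinySeqinfo(c(chr1 = 1000L))

test_that("Tn5 cut-site inference applies the +4/-5 strand shifts", {
  # 0-based [100,150) on the plus strand -> insertion point 104
  plus <- GRanges("chr1", IRanges(101, 150), strand = "+", seqinfo = si1k)
  cut <- inferCutSites(plus)
  expect_equal(start(cut) - 1L, 104L)
  expect_equal(width(cut), 1L)
  # minus strand, exclusive end 150 -> 145
  minus <- GRanges("chr1", IRanges(101, 150), strand = "-", seqinfo = si1k)
  expect_equal(start(inferCutSites(minus)) - 1L, 145L)
  # fragment [100,200): both ends, no extra shift
  frag <- GRanges("chr1", IRanges(101, 200), barcode = "AA", count = 1L,
                  seqinfo = si1k)
  expect_equal(sort(start(inferCutSites(frag)) - 1L), c(100L, 199L))
  # unstranded reads are rejected in read mode
  un <- GRanges("chr1", IRanges(101, 150), seqinfo = si1k)
  expect_error(inferCutSites(un, mode = "reads"), "strand")
})

test_that("cut-site smoothing yields clamped 40bp windows", {
  pt <- GRanges("chr1", IRanges(105, 105), seqinfo = si1k)  # 0-based point 104
  w <- smoothCutSites(pt)
  expect_equal(c(start(w) - 1L, end(w)), c(84L, 124L))  # [84,124)
  expect_equal(width(w), 40L)
  edge <- GRanges("chr1", IRanges(6, 6), seqinfo = si1k)  # 0-based point 5
  we <- smoothCutSites(edge)
  expect_equal(c(start(we) - 1L, end(we)), c(0L, 25L))
  # flank 0 degenerates to the 1bp cut-site base
  w0 <- smoothCutSites(pt, signalConfig(smooth_flank = 0))
  expect_equal(width(w0), 1L)
})

test_that("RP20M scale factor follows target_depth / depth", {
  expect_equal(rp20mScaleFactor(2e7), 1.0)
  expect_equal(rp20mScaleFactor(4e7), 0.5)
  expect_equal(rp20mScaleFactor(1e7), 2.0)
  expect_error(rp20mScaleFactor(0), "> 0")
})

test_that("coverage tracks count overlapping intervals times the scale", {
  iv <- GRanges("chr1", IRanges(c(1, 21), c(40, 60)), seqinfo = si1k)
  tr <- coverageTrack(iv, 1)
  v <- denseTrack(tr, "chr1")
  expect_equal(v[31], 2)  # 0-based base 30
  expect_equal(v[11], 1)
  expect_equal(sum(v), 80)
  expect_equal(sum(denseTrack(coverageTrack(GRanges(seqinfo = si1k), 1),
                              "chr1")), 0)
  expect_equal(denseTrack(coverageTrack(iv[1], 0.5), "chr1")[5], 0.5)
})

test_that("replicate averaging is the per-base mean", {
  t1 <- trackFromVectors(list(chrT = c(1, 3)))
  t2 <- trackFromVectors(list(chrT = c(3, 1)))
  expect_equal(denseTrack(averageReplicates(list(t1, t2)), "chrT"), c(2, 2))
  expect_equal(denseTrack(averageReplicates(list(t1)), "chrT"), c(1, 3))
  set.seed(3)
  vs <- replicate(3, runif(50), simplify = FALSE)
  tracks <- lapply(vs, function(v) trackFromVectors(list(chrT = v)))
  expect_equal(denseTrack(averageReplicates(tracks), "chrT"),
               (vs[[1]] + vs[[2]] + vs[[3]]) / 3)
  bad <- trackFromVectors(list(other = c(1, 2)))
  expect_error(averageReplicates(list(t1, bad)), "mismatched")
})

test_that("min-max fitting is nearest-rank over nonzero bases", {
  v <- c(numeric(100), 1:100)  # zeros must not enter the percentile
  tr <- trackFromVectors(list(chrT = v))
  expect_equal(fitMinMax(tr, 99)@max_p, 99)
  expect_equal(fitMinMax(tr, 100)@max_p, 100)
  const <- trackFromVectors(list(chrT = rep(c(0, 7), c(10, 30))))
  expect_equal(fitMinMax(const, 42)@max_p, 7)
  expect_error(fitMinMax(trackFromVectors(list(chrT = numeric(10)))),
               "all-zero")
  # run-length weighting matches the expanded multiset
  set.seed(9)
  vals <- sample(1:20, 8)
  mult <- sample(1:5, 8, replace = TRUE)
  tr2 <- trackFromVectors(list(chrT = rep(vals, mult)))
  for (p in c(25, 50, 90, 99))
    expect_equal(fitMinMax(tr2, p)@max_p, bruteNearestRank(vals, mult, p))
})

test_that("min-max normalization maps max_p to 1 and clips above", {
  tr <- trackFromVectors(list(chrT = c(0, 2, 4, 8)))
  params <- MinMaxParams(0, 4, 99)
  norm <- minmaxNormalize(tr, params)
  expect_equal(denseTrack(norm, "chrT"), c(0, 0.5, 1, 1))
  expect_equal(normalizationState(norm), "minmax")
  noclip <- minmaxNormalize(tr, params, clip = FALSE)
  expect_equal(denseTrack(noclip, "chrT"), c(0, 0.5, 1, 2))
})

test_that("min-max normalization is scale-equivariant", {
  set.seed(5)
  v <- c(numeric(40), rexp(60))
  for (c_ in c(0.5, 3)) {
    a <- trackFromVectors(list(chrT = v))
    b <- trackFromVectors(list(chrT = c_ * v))
    na <- minmaxNormalize(a, fitMinMax(a, 95))
    nb <- minmaxNormalize(b, fitMinMax(b, 95))
    expect_equal(denseTrack(na, "chrT"), denseTrack(nb, "chrT"))
  }
})

test_that("blacklist removal drops points, zeroes tracks and is idempotent", {
  bl <- GRanges("chr1", IRanges(91, 110))  # 0-based [90,110)
  pt <- GRanges("chr1", IRanges(101, 101), seqinfo = si1k)
  expect_length(applyBlacklist(pt, bl), 0L)
  outside <- GRanges("chr1", IRanges(300, 300), seqinfo = si1k)
  expect_equal(applyBlacklist(outside, bl), outside)

  tr <- trackFromVectors(list(chr1 = rep(1, 1000)))
  z <- applyBlacklist(tr, bl)
  v <- denseTrack(z, "chr1")
  expect_equal(sum(v == 0), 20)
  expect_equal(denseTrack(applyBlacklist(z, bl), "chr1"), v)
  whole <- applyBlacklist(tr, GRanges("chr1", IRanges(1, 1000)))
  expect_equal(sum(denseTrack(whole, "chr1")), 0)
})

test_that("fragment downsampling is uniform, seeded and bounded", {
  fx <- getFixture(11L)
  frags <- fx$truth$cellTypes[[1]]$fragments
  n <- length(frags)
  expect_error(downsampleFragments(frags, n + 1L, 1L), "only")
  all_ <- downsampleFragments(frags, n, 1L)
  expect_equal(sort(start(all_)), sort(start(frags)))
  expect_identical(downsampleFragments(frags, 500L, 7L),
                   downsampleFragments(frags, 500L, 7L))
  # halving the library halves mean coverage (within 5% across seeds)
  ratios <- vapply(1:10, function(s) {
    half <- downsampleFragments(frags, n %/% 2L, s)
    sum(as.numeric(width(half))) / sum(as.numeric(width(frags)))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.025)
})

test_that("prepared signal obeys the end-to-end mass identity", {
  fx <- getFixture(11L)
  frags <- fx$truth$cellTypes[[1]]$fragments
  si <- fx$truth$seqinfo
  prep <- prepareSignal(frags, si, blacklist = NULL, mode = "fragments")
  totalRaw <- sum(vapply(names(seqlengths(si)), function(chr)
    sum(denseTrack(prep$raw, chr)), numeric(1)))
  # 2 cut sites per fragment, 40bp each, minus boundary clamping
  expect_lte(totalRaw, 40 * prep$depth)
  expect_gt(totalRaw, 0.99 * 40 * prep$depth)
  totalRp <- sum(vapply(names(seqlengths(si)), function(chr)
    sum(denseTrack(prep$rp20m, chr)), numeric(1)))
  expect_equal(totalRp, totalRaw * 2e7 / prep$depth, tolerance = 1e-9)
  expect_lte(max(denseTrack(prep$minmax, "chr1")), 1)
})
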