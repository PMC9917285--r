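test_that("chromosome split defaults match the published partitions", {
  sp <- chromosomeSplit()
  expect_setequal(sp$train, paste0("chr", c(3:7, 9:11, 13:18, 20)))
  expect_setequal(sp$validation, c("chr2", "chr19"))
  expect_setequal(sp$test, c("chr1", "chr8"))
  expect_error(chromosomeSplit(train = "chr1"), "disjoint")
})

test_that("bin labels require strictly more than half-bin overlap", {
  si <- tinySeqinfo(c(chrT = 5000L))
  window <- GRanges("chrT", IRanges(1001, 2024), seqinfo = si)  # 1,024bp
  # bin 1 covers 0-based [1000,1032)
  fully <- GRanges("chrT", IRanges(901, 1100))
  expect_equal(makeLabels(fully, window)[1], 1L)
  # exactly 16 of 32 bp is NOT enough
  half <- GRanges("chrT", IRanges(1001, 1016))
  expect_equal(makeLabels(half, window)[1], 0L)
  over <- GRanges("chrT", IRanges(1001, 1017))  # 17bp
  expect_equal(makeLabels(over, window)[1], 1L)
  expect_equal(sum(makeLabels(GRanges(), window)), 0L)
  # two abutting peaks jointly covering a bin count through their union
  two <- GRanges("chrT", IRanges(c(1001, 1013), c(1012, 1026)))
  expect_equal(makeLabels(two, window)[1], 1L)
})

test_that("the ROI pool unions tagged peaks on partition chromosomes only", {
  fx <- getFixture(11L)
  split <- chromosomeSplit()
  pool <- buildRoiPool(fx$cells, split, "train", fx$truth$blacklist)
  expect_true(all(as.character(seqnames(pool)) %in% split$train))
  expect_setequal(unique(pool$origin_class), c("ATAC", "ChIP"))
  expect_setequal(unique(pool$origin_cell), names(fx$cells))
  expected <- sum(vapply(fx$cells, function(ct) {
    onTrain <- function(gr) sum(as.character(seqnames(gr)) %in% split$train)
    onTrain(ct@atacPeaks) + onTrain(ct@chipPeaks)
  }, numeric(1)))
  # only blacklist overlaps may reduce the count
  expect_lte(length(pool), expected)
  expect_gte(length(pool), 0.8 * expected)
  expect_false(any(overlapsAny(pool, fx$truth$blacklist)))
  noVal <- chromosomeSplit(train = "chr9", validation = "chr2",
                           test = "chr1")
  expect_error(buildRoiPool(fx$cells, noVal, "train"), "empty")
})

test_that("sampled examples pair signal and labels from one cell type", {
  fx <- getFixture(11L)
  split <- chromosomeSplit()
  pool <- buildRoiPool(fx$cells, split, "train", fx$truth$blacklist)
  cfg <- trainConfig(random_ratio = 0, pan_cell = FALSE, seed = 1L)
  set.seed(2)
  ex <- sampleExamples(pool, fx$cells, fx$truth$genome, split$train, cfg, 40L,
                       blacklist = fx$truth$blacklist)
  # cell-type-specific sampling: every example keeps its interval's origin
  mids <- (start(ex$windows) + end(ex$windows)) %/% 2L
  poolMids <- (start(pool) + end(pool)) %/% 2L
  for (i in seq_len(40L)) {
    j <- which(as.character(seqnames(pool)) ==
                 as.character(seqnames(ex$windows)[i]) & poolMids %in%
                 (mids[i] + c(-1L, 0L, 1L)))
    expect_true(ex$cellType[i] %in% pool$origin_cell[j])
  }
  # labels match the reference labeler for the sampled cell type
  for (i in seq_len(10L)) {
    ct <- fx$cells[[ex$cellType[i]]]
    expect_equal(ex$labels[, i], makeLabels(ct@chipPeaks, ex$windows[i]))
    sig <- bindcast:::windowSignal(ct@atacTrack,
                                   as.character(seqnames(ex$windows)[i]),
                                   start(ex$windows)[i], end(ex$windows)[i])
    expect_equal(ex$X[, 5L, i], sig)
  }
  # no window leaves the training chromosomes
  expect_true(all(as.character(seqnames(ex$windows)) %in% split$train))
})

test_that("random-ratio windows avoid the blacklist and ignore the pool", {
  fx <- getFixture(11L)
  split <- chromosomeSplit()
  pool <- buildRoiPool(fx$cells, split, "train", fx$truth$blacklist)
  cfg <- trainConfig(random_ratio = 1, seed = 1L)
  set.seed(3)
  ex <- sampleExamples(pool, fx$cells, fx$truth$genome, split$train, cfg, 50L,
                       blacklist = fx$truth$blacklist)
  expect_true(all(ex$random))
  expect_false(any(overlapsAny(ex$windows, fx$truth$blacklist)))
  expect_true(all(as.character(seqnames(ex$windows)) %in% split$train))
})

test_that("reverse-complement augmentation is an involution", {
  set.seed(6)
  ex <- list(X = array(0, c(16, 5, 1)), labels = matrix(0L, 4, 1))
  ex$X[, 1:4, 1] <- oneHotDNA(paste(sample(c("A", "C", "G", "T"), 16,
                                           replace = TRUE), collapse = ""))
  ex$X[, 5, 1] <- runif(16)
  ex$labels[, 1] <- c(1L, 0L, 0L, 0L)
  rc <- reverseComplementAugment(ex)
  expect_equal(rc$labels[, 1], c(0L, 0L, 0L, 1L))
  expect_equal(rc$X[, 5, 1], rev(ex$X[, 5, 1]))
  expect_equal(reverseComplementAugment(rc), ex)
  # all-A becomes all-T
  allA <- list(X = array(0, c(8, 5, 1)), labels = matrix(0L, 2, 1))
  allA$X[, 1, 1] <- 1
  flipped <- reverseComplementAugment(allA)
  expect_equal(flipped$X[, 4, 1], rep(1, 8))
  expect_equal(sum(flipped$X[, 1:3, 1]), 0)
})

test_that("training is reproducible and degenerates gracefully on empty labels", {
  fx <- getFixture(11L)
  split <- chromosomeSplit()
  spec <- tinySpec(inputLength = 1024L, outputBins = 32L, nBlocks = 2L,
                   kernelWidth = 7L, baseFilters = 4L,
                   dilationSchedule = c(1L, 2L, 4L))
  cfg <- trainConfig(epochs = 2L, batches_per_epoch = 3L, batch_size = 16L,
                     val_examples = 32L, seed = 9L)
  m1 <- trainModel(buildModel(spec, 9L), fx$cells, fx$truth$genome, split,
                   cfg, fx$truth$blacklist)
  m2 <- trainModel(buildModel(spec, 9L), fx$cells, fx$truth$genome, split,
                   cfg, fx$truth$blacklist)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_true(m1@trained)
  expect_equal(nrow(trainingHistory(m1)), 2L)

  # a TF that binds nowhere: the model converges toward all-low scores
  unbound <- lapply(fx$cells, function(ct)
    cellTypeData(ct@name, ct@atacTrack, ct@atacPeaks,
                 GRanges(seqinfo = fx$truth$seqinfo)))
  cfg2 <- trainConfig(epochs = 10L, batches_per_epoch = 10L, batch_size = 16L,
                      val_examples = 32L, seed = 9L)
  m0 <- trainModel(buildModel(spec, 9L), unbound, fx$truth$genome, split,
                   cfg2, fx$truth$blacklist)
  pool0 <- buildRoiPool(unbound, split, "train", fx$truth$blacklist)
  set.seed(1)
  ex <- sampleExamples(pool0, unbound, fx$truth$genome, split$train, cfg2,
                       32L, blacklist = fx$truth$blacklist)
  expect_lt(mean(predictWindows(m0, ex$X)), 0.1)
})
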