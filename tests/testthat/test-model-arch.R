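test_that("filter counts follow truncated 1.5x growth from 15", {
  spec <- architectureSpec()
  expect_equal(vapply(1:5, function(k) blockFilters(spec, k), integer(1)),
               c(15L, 22L, 33L, 50L, 75L))
  expect_error(blockFilters(spec, 6), "out of range")
  expect_error(blockFilters(spec, 0), "out of range")
  # non-decreasing for any growth >= 1
  for (g in c(1, 1.2, 2)) {
    s <- architectureSpec(filterGrowth = g)
    f <- vapply(1:5, function(k) blockFilters(s, k), integer(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("built models map any valid input to outputBins sigmoid scores", {
  m <- buildModel(architectureSpec(), seed = 1L)
  zero <- matrix(0, 1024, 5)
  p <- predictWindows(m, zero)
  expect_equal(nrow(p), 32L)
  expect_true(all(p > 0 & p < 1))
  # determinism: same seed gives identical initial predictions
  m2 <- buildModel(architectureSpec(), seed = 1L)
  set.seed(77)
  X <- array(runif(1024 * 5 * 2), dim = c(1024, 5, 2))
  expect_identical(predictWindows(m, X), predictWindows(m2, X))
  expect_false(identical(predictWindows(buildModel(architectureSpec(), 2L), X),
                         predictWindows(m, X)))
  # halved output resolution: 16 bins over the same 1,024bp input
  m16 <- buildModel(architectureSpec(outputBins = 16L), seed = 1L)
  expect_equal(nrow(predictWindows(m16, zero)), 16L)
  # impossible pooling arrangements are rejected
  expect_error(architectureSpec(outputBins = 24L), "power of poolWidth")
})

test_that("analytic receptive field matches closed forms and the paper-scale spec", {
  one <- architectureSpec(inputLength = 32L, inputChannels = 5L, nBlocks = 1L,
                          layersPerBlock = 1L, kernelWidth = 7L,
                          baseFilters = 4L, dilationSchedule = 1L,
                          poolWidth = 2L, outputBins = 32L)
  rf1 <- receptiveField(one)
  expect_equal(as.integer(rf1), 3L)        # one-sided of a 7-tap conv
  expect_equal(attr(rf1, "total"), 7)
  two <- architectureSpec(inputLength = 32L, inputChannels = 5L, nBlocks = 1L,
                          layersPerBlock = 2L, kernelWidth = 7L,
                          baseFilters = 4L, dilationSchedule = 1L,
                          poolWidth = 2L, outputBins = 32L)
  expect_equal(attr(receptiveField(two), "total"), 13)
  expect_gte(as.integer(receptiveField(architectureSpec())), 512L)
})

test_that("analytic receptive field matches input perturbation on positive-weight networks", {
  for (cfg in list(list(nb = 2L, k = 3L, il = 64L, ob = 8L, dil = c(1L, 2L)),
                   list(nb = 2L, k = 5L, il = 64L, ob = 16L, dil = c(1L, 1L)),
                   list(nb = 3L, k = 3L, il = 128L, ob = 16L,
                        dil = c(1L, 2L, 4L)))) {
    spec <- architectureSpec(inputLength = cfg$il, inputChannels = 5L,
                             nBlocks = cfg$nb, layersPerBlock = 1L,
                             kernelWidth = cfg$k, baseFilters = 3L,
                             filterGrowth = 1.5, dilationSchedule = cfg$dil,
                             poolWidth = 2L, outputBins = cfg$ob)
    m <- buildModel(spec, seed = 1L)
    # positive constant weights so every perturbation propagates
    for (i in seq_along(m@params)) {
      if (m@params[[i]]$type %in% c("conv", "out")) {
        m@params[[i]]$W[] <- 0.05
        m@params[[i]]$b[] <- 0
      }
    }
    base <- matrix(0.1, spec@inputLength, 5L)
    p0 <- predictWindows(m, base)
    bin <- spec@outputBins %/% 2L  # central bin, away from boundaries
    affected <- vapply(seq_len(spec@inputLength), function(pos) {
      x <- base
      x[pos, ] <- x[pos, ] + 0.5
      abs(predictWindows(m, x)[bin, 1] - p0[bin, 1]) > 1e-12
    }, logical(1))
    rng <- range(which(affected))
    # a contiguous field whose total width matches the analytic value and
    # which contains the bin's anchor positions
    expect_true(all(affected[rng[1]:rng[2]]))
    expect_equal(rng[2] - rng[1] + 1L, as.integer(attr(receptiveField(spec),
                                                       "total")))
    binW <- spec@inputLength %/% spec@outputBins
    expect_lte(rng[1], (bin - 1L) * binW + 1L)
    expect_gte(rng[2], bin * binW)
  }
})

test_that("dice coefficient matches its closed forms", {
  expect_equal(diceCoefficient(c(1, 1, 0, 0), c(1, 1, 0, 0), epsilon = 0), 1)
  expect_equal(diceCoefficient(c(1, 1, 0, 0), c(0, 0, 1, 1), epsilon = 0), 0)
  expect_equal(diceCoefficient(c(1, 1, 0, 0), c(1, 0, 1, 0), epsilon = 0), 0.5)
  expect_error(diceCoefficient(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("binary cross-entropy matches the brute-force mean", {
  t <- c(1, 0, 1, 1)
  expect_lt(bceLoss(t, t), 1e-6)
  expect_equal(bceLoss(rep(0.5, 8), rbinom(8, 1, 0.5)), log(2))
  set.seed(21)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(bceLoss(p, y), -mean(y * log(p) + (1 - y) * log(1 - p)))
  expect_error(bceLoss(p, y[-1]), "equal length")
})

test_that("layer gradients agree with a double-precision reference", {
  set.seed(1)
  L <- 14L; Cin <- 3L; Cout <- 4L; B <- 2L; k <- 3L; d <- 2L
  X <- array(rnorm(L * Cin * B), c(L, Cin, B))
  W <- array(rnorm(k * Cin * Cout), c(k, Cin, Cout))
  b <- rnorm(Cout)
  S <- array(rnorm(L * Cout * B), c(L, Cout, B))
  for (relu in c(FALSE, TRUE)) {
    Y <- bindcast:::cpp_conv1d_fw(X, W, b, d, relu)
    expect_equal(Y, refConv(X, W, b, d, relu), tolerance = 1e-5)
    bw <- bindcast:::cpp_conv1d_bw(X, W, S, d, if (relu) Y else NULL)
    loss <- function(Xp, Wp, bp) sum(S * refConv(Xp, Wp, bp, d, relu))
    eps <- 1e-6
    gW <- array(0, dim(W))
    for (i in seq_along(W)) {
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      gW[i] <- (loss(X, Wp, b) - loss(X, Wm, b)) / (2 * eps)
    }
    expect_equal(as.numeric(bw$dW), as.numeric(gW), tolerance = 1e-4)
    gX <- array(0, dim(X))
    for (i in seq_along(X)) {
      Xp <- X; Xp[i] <- Xp[i] + eps
      Xm <- X; Xm[i] <- Xm[i] - eps
      gX[i] <- (loss(Xp, W, b) - loss(Xm, W, b)) / (2 * eps)
    }
    expect_equal(as.numeric(bw$dX), as.numeric(gX), tolerance = 1e-4)
  }
  # batch-norm backward (training statistics)
  g <- rnorm(Cin); be <- rnorm(Cin)
  S2 <- array(rnorm(L * Cin * B), c(L, Cin, B))
  bnf <- function(Xp) bindcast:::cpp_bn_fw(Xp, g, be, 1e-5, TRUE,
                                           numeric(Cin), rep(1, Cin), 0.9)
  r <- bnf(X)
  bb <- bindcast:::cpp_bn_bw(X, g, r$mean, r$var, S2, 1e-5)
  eps <- 1e-6
  gX <- array(0, dim(X))
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    gX[i] <- (sum(S2 * bnf(Xp)$Y) - sum(S2 * bnf(Xm)$Y)) / (2 * eps)
  }
  expect_equal(as.numeric(bb$dX), as.numeric(gX), tolerance = 1e-5)
  # max-pool backward routes gradient to the argmax
  pf <- bindcast:::cpp_maxpool_fw(X, 2L)
  S3 <- array(rnorm((L / 2) * Cin * B), c(L / 2, Cin, B))
  dX <- bindcast:::cpp_maxpool_bw(pf$amax, S3, L)
  gX <- array(0, dim(X))
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + 1e-6
    Xm <- X; Xm[i] <- Xm[i] - 1e-6
    gX[i] <- (sum(S3 * bindcast:::cpp_maxpool_fw(Xp, 2L)$Y) -
              sum(S3 * bindcast:::cpp_maxpool_fw(Xm, 2L)$Y)) / 2e-6
  }
  expect_equal(as.numeric(dX), as.numeric(gX), tolerance = 1e-6)
})

test_that("the training session optimizes and matches the reference forward", {
  set.seed(4)
  spec <- tinySpec()
  m <- buildModel(spec, seed = 4L)
  X <- array(runif(64 * 5 * 8), dim = c(64, 5, 8))
  Y <- matrix(rbinom(16 * 8, 1, 0.3), 16, 8)
  sess <- bindcast:::nn_session_new(m@params)
  l1 <- bindcast:::nn_session_train_batch(sess, X, Y, 1e-3)
  # the session's first-step loss equals the R-path loss on the same batch
  fw <- bindcast:::nnForward(m@params, X, training = TRUE)
  expect_equal(l1, bceLoss(fw$prob, Y), tolerance = 1e-5)
  # repeated steps on one memorizable batch drive the loss down
  for (i in 1:250) loss <- bindcast:::nn_session_train_batch(sess, X, Y, 2e-3)
  expect_lt(loss, 0.1)
  expect_lt(loss, l1 / 4)
  # exported parameters reproduce the session's fit through the R forward pass
  p <- bindcast:::nn_session_params(sess)
  prob <- bindcast:::nnForward(p, X, training = FALSE)$prob
  expect_equal(dim(prob), c(16L, 8L))
  expect_true(all(prob >= 0 & prob <= 1))
})
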