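# The dilated convolutional network: construction, forward/backward passes
# (on top of the compiled layer primitives), receptive field, dice and
# cross-entropy.

#' Filter count of a convolutional block
#'
#' Block k holds \code{trunc(baseFilters * filterGrowth^(k-1))} filters;
#' defaults give 15, 22, 33, 50, 75.
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @param k Block index (1-based).
#' @return Integer filter count.
#' @examples
#' blockFilters(architectureSpec(), 5)  # 75
#' @export
blockFilters <- function(spec, k) {
  if (k < 1L || k > spec@nBlocks)
    stop("block index ", k, " out of range 1..", spec@nBlocks)
  as.integer(trunc(spec@baseFilters * spec@filterGrowth^(k - 1)))
}

# The ordered layer plan implied by a spec: a list of descriptors
# (type conv/relu/bn/pool/out) with channel counts and dilations. Pooling
# stages are derived so that the output length equals outputBins; they are
# interleaved after the first blocks, with any surplus after the final
# dilated stage. Dilation entries beyond nBlocks drive a final
# layersPerBlock-deep convolutional stage preceding the sigmoid output.
layerPlan <- function(spec) {
  nPool <- as.integer(round(log(spec@inputLength / spec@outputBins) /
                            log(spec@poolWidth)))
  plan <- list()
  cin <- spec@inputChannels
  poolsLeft <- nPool
  for (k in seq_len(spec@nBlocks)) {
    cout <- blockFilters(spec, k)
    d <- spec@dilationSchedule[k]
    for (j in seq_len(spec@layersPerBlock)) {
      plan[[length(plan) + 1L]] <- list(type = "conv", cin = cin, cout = cout,
                                        k = spec@kernelWidth, dilation = d,
                                        act = "relu")
      cin <- cout
    }
    plan[[length(plan) + 1L]] <- list(type = "bn", c = cout)
    if (poolsLeft > 0L) {
      plan[[length(plan) + 1L]] <- list(type = "pool", width = spec@poolWidth)
      poolsLeft <- poolsLeft - 1L
    }
  }
  extra <- spec@dilationSchedule[-seq_len(spec@nBlocks)]
  for (d in extra) {
    for (j in seq_len(spec@layersPerBlock)) {
      plan[[length(plan) + 1L]] <- list(type = "conv", cin = cin, cout = cin,
                                        k = spec@kernelWidth, dilation = d,
                                        act = "relu")
    }
    plan[[length(plan) + 1L]] <- list(type = "bn", c = cin)
  }
  while (poolsLeft > 0L) {
    plan[[length(plan) + 1L]] <- list(type = "pool", width = spec@poolWidth)
    poolsLeft <- poolsLeft - 1L
  }
  plan[[length(plan) + 1L]] <- list(type = "out", cin = cin)
  plan
}

# Output length implied by the plan (for the construction-error contract).
planOutputLength <- function(spec) {
  L <- spec@inputLength
  for (l in layerPlan(spec)) if (l$type == "pool") L <- L %/% l$width
  L
}

#' Build a network from an architecture specification
#'
#' Weights are Glorot-uniform initialized (limit
#' \code{sqrt(6 / (fan_in + fan_out))}), deterministically for a fixed
#' seed. Batch-norm scale/shift start at 1/0 with running statistics 0/1.
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @param seed Integer seed for the initialization.
#' @return An untrained \linkS4class{ModelHandle}.
#' @export
buildModel <- function(spec, seed = 1L) {
  validObject(spec)
  Lout <- planOutputLength(spec)
  if (Lout != spec@outputBins)
    stop("inconsistent pooling/output configuration: the layer stack implies ",
         "an output length of ", Lout, ", not outputBins = ", spec@outputBins)
  plan <- layerPlan(spec)
  params <- withSeed(seed, lapply(plan, function(l) {
    switch(l$type,
      conv = {
        fan_in <- l$k * l$cin; fan_out <- l$k * l$cout
        lim <- sqrt(6 / (fan_in + fan_out))
        list(type = "conv",
             W = array(runif(l$k * l$cin * l$cout, -lim, lim),
                       dim = c(l$k, l$cin, l$cout)),
             b = numeric(l$cout), dilation = l$dilation, act = l$act)
      },
      bn = list(type = "bn", gamma = rep(1, l$c), beta = numeric(l$c),
                rmean = numeric(l$c), rvar = rep(1, l$c)),
      pool = list(type = "pool", width = l$width),
      out = {
        lim <- sqrt(6 / (l$cin + 1))
        list(type = "out",
             W = array(runif(l$cin, -lim, lim), dim = c(1L, l$cin, 1L)),
             b = 0, dilation = 1L)
      })
  }))
  new("ModelHandle", spec = spec, params = params, seed = as.integer(seed),
      trained = FALSE, history = data.frame())
}

# Batch-norm hyperparameters (shared by training and inference).
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Forward pass. X: array (L, channels, batch). Returns list(prob: bins x
# batch matrix, cache, params): in training mode batch statistics are used
# and running statistics updated (returned in params).
nnForward <- function(params, X, training = FALSE) {
  cache <- vector("list", length(params))
  for (i in seq_along(params)) {
    l <- params[[i]]
    if (l$type == "conv") {
      Y <- cpp_conv1d_fw(X, l$W, l$b, l$dilation, l$act == "relu")
      cache[[i]] <- list(X = X, Y = Y)  # Y referenced, not copied
      X <- Y
    } else if (l$type == "bn") {
      r <- cpp_bn_fw(X, l$gamma, l$beta, BN_EPS, training, l$rmean, l$rvar,
                     BN_MOMENTUM)
      cache[[i]] <- list(X = X, mean = r$mean, var = r$var)
      if (training) {
        params[[i]]$rmean <- as.numeric(r$running_mean)
        params[[i]]$rvar <- as.numeric(r$running_var)
      }
      X <- r$Y
    } else if (l$type == "pool") {
      r <- cpp_maxpool_fw(X, l$width)
      cache[[i]] <- list(amax = r$amax, Lin = dim(X)[1L])
      X <- r$Y
    } else if (l$type == "out") {
      cache[[i]] <- list(X = X)
      z <- cpp_conv1d_fw(X, l$W, l$b, 1L)
      prob <- 1 / (1 + exp(-z[, 1L, , drop = TRUE]))
      if (is.null(dim(prob))) prob <- matrix(prob, ncol = dim(z)[3L])
      return(list(prob = prob, z = z, cache = cache, params = params))
    }
  }
  stop("layer stack has no output layer")  # nocov
}

# Backward pass from d(loss)/d(presigmoid) (bins x batch). Returns the
# gradient list, aligned with params (NULL entries for parameter-free
# layers' missing tensors).
nnBackward <- function(params, cache, dz) {
  grads <- vector("list", length(params))
  i <- length(params)
  l <- params[[i]]
  dZ <- array(dz, dim = c(nrow(dz), 1L, ncol(dz)))
  r <- cpp_conv1d_bw(cache[[i]]$X, l$W, dZ, 1L)
  grads[[i]] <- list(dW = r$dW, db = as.numeric(r$db))
  dX <- r$dX
  for (i in rev(seq_len(length(params) - 1L))) {
    l <- params[[i]]
    if (l$type == "conv") {
      r <- cpp_conv1d_bw(cache[[i]]$X, l$W, dX, l$dilation,
                         if (l$act == "relu") cache[[i]]$Y else NULL)
      grads[[i]] <- list(dW = r$dW, db = as.numeric(r$db))
      dX <- r$dX
    } else if (l$type == "bn") {
      r <- cpp_bn_bw(cache[[i]]$X, l$gamma, cache[[i]]$mean, cache[[i]]$var,
                     dX, BN_EPS)
      grads[[i]] <- list(dgamma = as.numeric(r$dgamma),
                         dbeta = as.numeric(r$dbeta))
      dX <- r$dX
    } else if (l$type == "pool") {
      dX <- cpp_maxpool_bw(cache[[i]]$amax, dX, cache[[i]]$Lin)
    }
  }
  grads
}

# One ADAM update. state holds first/second moments per tensor; t is the
# step count (1-based).
adamInit <- function(params) {
  lapply(params, function(l) {
    if (l$type %in% c("conv", "out"))
      list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    else if (l$type == "bn")
      list(mg = numeric(length(l$gamma)), vg = numeric(length(l$gamma)),
           mb = numeric(length(l$beta)), vb = numeric(length(l$beta)))
    else NULL
  })
}

adamStep <- function(params, grads, state, t, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(theta, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(theta = theta - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(params)) {
    l <- params[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv", "out")) {
      u <- upd(l$W, g$dW, state[[i]]$mW, state[[i]]$vW)
      params[[i]]$W <- u$theta; state[[i]]$mW <- u$m; state[[i]]$vW <- u$v
      u <- upd(l$b, g$db, state[[i]]$mb, state[[i]]$vb)
      params[[i]]$b <- u$theta; state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    } else if (l$type == "bn") {
      u <- upd(l$gamma, g$dgamma, state[[i]]$mg, state[[i]]$vg)
      params[[i]]$gamma <- u$theta; state[[i]]$mg <- u$m; state[[i]]$vg <- u$v
      u <- upd(l$beta, g$dbeta, state[[i]]$mb, state[[i]]$vb)
      params[[i]]$beta <- u$theta; state[[i]]$mb <- u$m; state[[i]]$vb <- u$v
    }
  }
  list(params = params, state = state)
}

#' Forward pass of a model on a batch of windows
#'
#' @param model A \linkS4class{ModelHandle}.
#' @param X Array of dim (inputLength, inputChannels, batch), or a single
#'   inputLength x inputChannels matrix.
#' @return A outputBins x batch matrix of sigmoid scores in [0,1].
#' @export
predictWindows <- function(model, X) {
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  stopifnot(dim(X)[1L] == model@spec@inputLength,
            dim(X)[2L] == model@spec@inputChannels)
  nnForward(model@params, X, training = FALSE)$prob
}

#' Receptive field of the network
#'
#' One-sided extent, in input bp, of the receptive field of one unit of
#' the ultimate hidden layer, computed analytically by accumulating
#' (kernel-1) x dilation x cumulative-stride contributions through the
#' stack, and truncated at the input boundary (half the input length).
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @return Integer one-sided extent in bp; the full (two-sided) field is
#'   attached as attribute \code{"total"}.
#' @examples
#' receptiveField(architectureSpec())  # 512 (truncated at the 1,024bp input)
#' @export
receptiveField <- function(spec) {
  rf <- 1
  jump <- 1
  for (l in layerPlan(spec)) {
    if (l$type == "conv") rf <- rf + (l$k - 1) * l$dilation * jump
    else if (l$type == "pool") {
      rf <- rf + (l$width - 1) * jump
      jump <- jump * l$width
    }
  }
  oneSided <- min(floor((rf - 1) / 2), spec@inputLength %/% 2L)
  structure(as.integer(oneSided), total = rf)
}

#' Dice coefficient
#'
#' Soft dice overlap \code{(2 * sum(pred * target) + eps) /
#' (sum(pred) + sum(target) + eps)} between predictions in [0,1] and binary
#' targets; used for validation-based epoch selection.
#'
#' @param pred Numeric vector/matrix of predictions in [0,1].
#' @param target Binary vector/matrix of the same length.
#' @param epsilon Smoothing constant (default 1).
#' @return Numeric in [0,1].
#' @export
diceCoefficient <- function(pred, target, epsilon = 1) {
  if (length(pred) != length(target))
    stop("pred and target must have equal length")
  (2 * sum(pred * target) + epsilon) / (sum(pred) + sum(target) + epsilon)
}

#' Mean binary cross-entropy
#'
#' Predictions are clamped to [1e-7, 1 - 1e-7] before taking logs.
#'
#' @param pred Predictions in [0,1].
#' @param target Binary targets.
#' @return Mean BCE over all bins (>= 0).
#' @export
bceLoss <- function(pred, target) {
  if (length(pred) != length(target))
    stop("pred and target must have equal length")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}
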