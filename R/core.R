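#' Configuration of a convolutional core
#'
#' Defaults follow the standard architecture: kernel sizes 25, 9, 5, 5
#' (truncated to `nLayers`), a 2x2 max pool after layer 1, ELU activations,
#' no bias terms, depth-separable convolutions from layer 2 on. `activation =
#' "identity"` together with `poolType = "avg"` gives the LN-model core;
#' `activation = "relu"` is the minimodel convention.
#'
#' @param nLayers number of convolutional layers (1-4).
#' @param channels per-layer channel counts (recycled/truncated to `nLayers`);
#'   default 16 then 320.
#' @param kernelSizes per-layer odd kernel sizes.
#' @param activation "elu", "relu" or "identity".
#' @param poolType "max" or "avg" (2x2, stride 2, after layer 1).
#' @return a config list for [newConvCore()].
#' @export
coreConfig <- function(nLayers = 2L,
                       channels = c(16L, 320L, 320L, 320L),
                       kernelSizes = c(25L, 9L, 5L, 5L),
                       activation = c("elu", "relu", "identity"),
                       poolType = c("max", "avg")) {
  activation <- match.arg(activation)
  poolType <- match.arg(poolType)
  nLayers <- as.integer(nLayers)
  channels <- as.integer(rep_len(channels, 4L))
  kernelSizes <- as.integer(rep_len(kernelSizes, 4L))
  list(nLayers = nLayers, channels = channels, kernelSizes = kernelSizes,
       activation = activation, poolType = poolType)
}

xavierConv <- function(kh, kw, cin, cout) {
  a <- sqrt(6 / (kh * kw * cin + kh * kw * cout))
  array(runif(kh * kw * cout, -a, a), c(kh, kw, cout))
}

#' Create a randomly initialized convolutional core
#'
#' Convolution kernels use Xavier initialization; batch-norm scale/shift start
#' at 1/0 with running statistics 0/1.
#'
#' @param config a list from [coreConfig()].
#' @param seed integer seed.
#' @return a [ConvCore-class].
#' @export
newConvCore <- function(config = coreConfig(), seed = 1L) {
  withSeed(seed, {
    layers <- vector("list", config$nLayers)
    for (l in seq_len(config$nLayers)) {
      k <- config$kernelSizes[l]
      cout <- config$channels[l]
      if (l == 1L) {
        layers[[l]] <- list(
          kernels = xavierConv(k, k, 1L, cout), mix = NULL,
          gamma = rep(1, cout), beta = rep(0, cout),
          runMean = rep(0, cout), runVar = rep(1, cout))
      } else {
        cin <- config$channels[l - 1L]
        a <- sqrt(6 / (cin + cout))
        layers[[l]] <- list(
          kernels = xavierConv(k, k, 1L, cin), # depthwise spatial, one per input
          mix = matrix(runif(cin * cout, -a, a), cin, cout),
          gamma = rep(1, cout), beta = rep(0, cout),
          runMean = rep(0, cout), runVar = rep(1, cout))
      }
    }
    new("ConvCore", config = config, layers = layers)
  })
}

bnEps <- 1e-5
bnMomentum <- 0.1

# apply batch norm to a (H, W, N, C) feature array; mode "eval" uses the
# stored running statistics, "train" uses batch statistics and returns them
applyBatchNorm <- function(x, layer, mode = "eval") {
  d <- dim(x)
  C <- d[4L]
  m2 <- matrix(x, ncol = C)
  if (mode == "train") {
    mu <- colMeans(m2)
    v <- colMeans(m2^2) - mu^2
  } else {
    mu <- layer$runMean
    v <- layer$runVar
  }
  inv <- 1 / sqrt(v + bnEps)
  y <- sweep(m2, 2L, mu, `-`)
  y <- sweep(y, 2L, layer$gamma * inv, `*`)
  y <- sweep(y, 2L, layer$beta, `+`)
  dim(y) <- d
  if (mode == "train") attr(y, "batchStats") <- list(mean = mu, var = v)
  y
}

avgPool2 <- function(x) {
  d <- dim(x)
  h2 <- d[1L] %/% 2L
  w2 <- d[2L] %/% 2L
  x <- x[seq_len(2L * h2), seq_len(2L * w2), , , drop = FALSE]
  0.25 * (x[c(TRUE, FALSE), c(TRUE, FALSE), , , drop = FALSE] +
          x[c(FALSE, TRUE), c(TRUE, FALSE), , , drop = FALSE] +
          x[c(TRUE, FALSE), c(FALSE, TRUE), , , drop = FALSE] +
          x[c(FALSE, TRUE), c(FALSE, TRUE), , , drop = FALSE])
}

#' Forward pass of a convolutional core
#'
#' Applies, per layer, convolution (no bias) -> batch normalization ->
#' activation, with a 2x2 pool (max, or average for the LN core) after
#' layer 1. Convolutions use "same" zero padding, so feature maps keep the
#' image resolution except for the single 2x pool. In evaluation mode
#' (default) batch norm uses the stored running statistics and the pass is
#' deterministic.
#'
#' @param core a [ConvCore-class].
#' @param imgs numeric array `(H, W, N)` of images, or a [StimulusSet-class].
#' @param upto compute through this many layers (default: all).
#' @return feature array `(H', W', N, C)`.
#' @export
coreForward <- function(core, imgs, upto = core@config$nLayers) {
  if (is(imgs, "StimulusSet")) imgs <- images(imgs)
  d <- dim(imgs)
  stopIfNot(length(d) == 3L, "imgs must be an (H, W, N) array")
  cfg <- core@config
  k1 <- cfg$kernelSizes[1L]
  stopIfNot(d[1L] >= k1 && d[2L] >= k1,
            "image spatial dims must be >= the layer-1 kernel size")
  x <- NULL
  for (l in seq_len(upto)) {
    layer <- core@layers[[l]]
    if (l == 1L) {
      x <- conv1EvalPooled(layer, imgs, cfg$activation, cfg$poolType)
      next
    } else {
      x <- cc_dwconv_forward(x, layer$kernels)
      d4 <- dim(x)
      m2 <- matrix(x, ncol = d4[4L]) %*% layer$mix
      dim(m2) <- c(d4[1L], d4[2L], d4[3L], ncol(layer$mix))
      x <- m2
    }
    x <- applyBatchNorm(x, layer, mode = "eval")
    xa <- applyActivation(x, cfg$activation)
    dim(xa) <- dim(x)
    x <- xa
  }
  x
}

#' Calibrate the running batch-norm statistics of a core
#'
#' Sets each layer's running mean/variance to the empirical per-channel
#' moments of its pre-normalization activations on a calibration stimulus
#' set, so that evaluation-mode responses are standardized. Used when
#' constructing ground-truth cores that are never trained.
#'
#' @param core a [ConvCore-class].
#' @param imgs calibration images, array `(H, W, N)` or [StimulusSet-class].
#' @return the core with updated running statistics.
#' @export
calibrateCore <- function(core, imgs, chunk = 128L) {
  if (is(imgs, "StimulusSet")) imgs <- images(imgs)
  cfg <- core@config
  n <- dim(imgs)[3L]
  # layer 1: accumulate pre-normalization moments over image blocks
  layer <- core@layers[[1L]]
  C <- dim(layer$kernels)[3L]
  s1 <- s2 <- rep(0, C)
  cnt <- 0
  for (s in seq(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    pre <- cc_conv1_forward(imgs[, , ix, drop = FALSE], layer$kernels)
    m2 <- matrix(pre, ncol = C)
    s1 <- s1 + colSums(m2)
    s2 <- s2 + colSums(m2^2)
    cnt <- cnt + nrow(m2)
  }
  core@layers[[1L]]$runMean <- s1 / cnt
  core@layers[[1L]]$runVar <- pmax(s2 / cnt - (s1 / cnt)^2, 1e-12)
  x <- conv1EvalPooled(core@layers[[1L]], imgs, cfg$activation, cfg$poolType,
                       chunk = chunk)
  for (l in seq_len(cfg$nLayers)[-1L]) {
    layer <- core@layers[[l]]
    pre <- cc_dwconv_forward(x, layer$kernels)
    d4 <- dim(pre)
    m2 <- matrix(pre, ncol = d4[4L]) %*% layer$mix
    dim(m2) <- c(d4[1L], d4[2L], d4[3L], ncol(layer$mix))
    pre <- m2
    m2 <- matrix(pre, ncol = dim(pre)[4L])
    core@layers[[l]]$runMean <- colMeans(m2)
    core@layers[[l]]$runVar <- pmax(colMeans(m2^2) - colMeans(m2)^2, 1e-12)
    x <- applyBatchNorm(pre, core@layers[[l]], mode = "eval")
    xa <- applyActivation(x, cfg$activation)
    dim(xa) <- dim(x)
    x <- xa
  }
  core
}

# layer-1 eval pass (conv -> BN eval -> activation -> 2x pool), processed in
# image blocks so the un-pooled activations never materialize for the full
# stimulus set
conv1EvalPooled <- function(layer, imgs, activation, poolType,
                            chunk = 128L) {
  d <- dim(imgs)
  C <- dim(layer$kernels)[3L]
  n <- d[3L]
  out <- array(0, c(d[1L] %/% 2L, d[2L] %/% 2L, n, C))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    ix <- s:min(s + chunk - 1L, n)
    x <- cc_conv1_forward(imgs[, , ix, drop = FALSE], layer$kernels)
    x <- applyBatchNorm(x, layer, mode = "eval")
    a <- applyActivation(x, activation)
    dim(a) <- dim(x)
    p <- if (poolType == "max") cc_maxpool2(a)$y else avgPool2(a)
    out[, , ix, ] <- p
  }
  out
}

#' Frozen conv1 features of a minimodel-style first layer
#'
#' conv -> batch norm (running statistics) -> ReLU -> 2x2 max pool, the fixed
#' first stage shared by all minimodels. Computing these once and reusing
#' them across neurons is the main computational saving of per-neuron fits.
#'
#' @param conv1 a 1-layer [ConvCore-class].
#' @param imgs array `(H, W, N)` or a [StimulusSet-class].
#' @return feature array `(H/2, W/2, N, C1)`.
#' @export
conv1Features <- function(conv1, imgs) {
  if (is(imgs, "StimulusSet")) imgs <- images(imgs)
  conv1EvalPooled(conv1@layers[[1L]], imgs, "relu", "max")
}

#' Build a structured conv1 filter bank
#'
#' A 1-layer core whose kernels are Gabor filters spanning orientations,
#' spatial frequencies and phases (the qualitative structure that population
#' models recover in layer 1), with batch-norm statistics calibrated on a
#' stimulus set so evaluation-mode outputs are standardized.
#'
#' @param stimuli calibration [StimulusSet-class] (or `(H, W, N)` array).
#' @param nChannels number of kernels (default 16).
#' @param kernelSize odd kernel size (default 25).
#' @param seed integer seed (jitters filter parameters).
#' @param activation core activation for downstream use.
#' @return a calibrated 1-layer [ConvCore-class].
#' @export
makeConv1Bank <- function(stimuli, nChannels = 16L, kernelSize = 25L,
                          seed = 1L, activation = "relu") {
  cfg <- coreConfig(nLayers = 1L, channels = nChannels,
                    kernelSizes = kernelSize, activation = activation)
  core <- newConvCore(cfg, seed = seed)
  kernels <- withSeed(seed + 1L, {
    arr <- array(0, c(kernelSize, kernelSize, nChannels))
    for (i in seq_len(nChannels)) {
      theta <- (i - 1) * pi / nChannels + runif(1, -0.1, 0.1)
      lambda <- runif(1, 6, 14)            # wavelength in px
      psi <- runif(1, 0, 2 * pi)
      sigma <- lambda * runif(1, 0.4, 0.6)
      g <- gaborKernel(kernelSize, kernelSize,
                       cy = (kernelSize + 1) / 2, cx = (kernelSize + 1) / 2,
                       f = sigma / lambda, theta = theta, psi = psi,
                       alpha = sigma, beta = 1.2)
      arr[, , i] <- g / sqrt(sum(g^2))
    }
    arr
  })
  core@layers[[1L]]$kernels <- kernels
  calibrateCore(core, stimuli)
}
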