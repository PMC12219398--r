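# build the I x J repeat matrix of one neuron over a set of images
repeatMatrix <- function(responseSet, neuron, imageIdx) {
  pres <- presentationMap(responseSet)
  y <- responses(responseSet)[, neuron]
  lapply(imageIdx, function(i) y[pres$image == i])
}

#' Decode texture category from population responses
#'
#' Fits a multinomial logistic decoder (L2 strength `decay`) on the
#' single-trial responses to the training exemplars, after z-scoring each
#' neuron with its training mean and standard deviation, and reports top-1
#' accuracy on the repeat-averaged test exemplars (standardized with the
#' same training statistics, so accuracy is invariant to per-neuron affine
#' rescaling of the responses).
#'
#' @param responseSet a [ResponseSet-class] with category annotations.
#' @param stimuli the generating [TextureStimulusSet-class].
#' @param decay L2 regularization strength (default 10).
#' @param seed integer seed (used when shuffling labels).
#' @param shuffleLabels permute training and test labels (chance-level
#'   control).
#' @return top-1 accuracy on test exemplars, with attribute `"nTest"`.
#' @export
decodeCategories <- function(responseSet, stimuli, decay = 10, seed = 1L,
                             shuffleLabels = FALSE) {
  split <- splitLabels(stimuli)
  catImg <- categoryIndex(stimuli)
  stopIfNot(length(unique(catImg)) >= 2L, "need >= 2 categories")
  pres <- presentationMap(responseSet)
  Y <- responses(responseSet)
  trainRows <- which(split[pres$image] == "train")
  testImgs <- which(split == "test")
  stopIfNot(length(trainRows) > 0 && length(testImgs) > 0,
            "need train and test exemplars")
  Xtr <- Y[trainRows, , drop = FALSE]
  ytr <- catImg[pres$image[trainRows]]
  # repeat-averaged test responses
  Xte <- t(vapply(testImgs, function(i)
    colMeans(Y[pres$image == i, , drop = FALSE]), numeric(ncol(Y))))
  yte <- catImg[testImgs]
  if (shuffleLabels) {
    perm <- withSeed(seed, list(tr = sample(length(ytr)),
                                te = sample(length(yte))))
    ytr <- ytr[perm$tr]
    yte <- yte[perm$te]
  }
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu, `-`), 2L, sd_, `/`)
  Xte <- sweep(sweep(Xte, 2L, mu, `-`), 2L, sd_, `/`)
  df <- data.frame(y = factor(ytr), Xtr)
  fit <- nnet::multinom(y ~ ., data = df, decay = decay, trace = FALSE,
                        maxit = 300, MaxNWts = 1e6)
  pred <- predict(fit, newdata = data.frame(Xte))
  structure(mean(as.character(pred) == as.character(yte)),
            nTest = length(yte))
}

# mean FECV over the columns of an (trials x units) activation matrix,
# skipping degenerate units
fecvOverUnits <- function(mat, category) {
  vals <- apply(mat, 2L, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressMessages(as.numeric(fecvPairwise(v, category)))
  })
  mean(vals, na.rm = TRUE)
}

#' Stage-wise category variance of a minimodel
#'
#' Computes the fraction of explainable category variance ([fecvPairwise()])
#' of the model's noiseless activations after each successive operation:
#' conv1 (+batch norm+ReLU), 2x2 max pool, conv2 spatial convolution, 1x1
#' mix (+batch norm+ReLU), spatial pooling with `W_xy`, and the readout
#' output. Spatial stages are aggregated by computing the FECV per channel on
#' globally averaged activations (on `W_xy`-pooled activations for the
#' post-conv2 pooling stage) and averaging across channels; degenerate
#' (zero-variance) channels are flagged by omission.
#'
#' @param minimodel a [Minimodel-class].
#' @param textures a (spectrum-matched) [TextureStimulusSet-class].
#' @param sharedStages optional output of [precomputeConv1Stages()] reused
#'   across neurons.
#' @return named numeric vector of 6 per-stage FECV values, in order.
#' @export
stagewiseFECV <- function(minimodel, textures, sharedStages = NULL) {
  category <- categoryIndex(textures)
  if (is.null(sharedStages))
    sharedStages <- precomputeConv1Stages(minimodel@conv1, textures)
  pooled1 <- sharedStages$pooled1
  d <- dim(pooled1)
  s2 <- cc_dwconv_forward(pooled1, minimodel@conv2Spatial)
  u <- matrix(s2, ncol = d[4L]) %*% minimodel@conv2Mix
  m <- ncol(minimodel@conv2Mix)
  inv <- 1 / sqrt(minimodel@bnVar + bnEps)
  u <- sweep(u, 2L, minimodel@bnMean, `-`)
  u <- sweep(u, 2L, minimodel@bnGamma * inv, `*`)
  u <- sweep(u, 2L, minimodel@bnBeta, `+`)
  act2 <- pmax(u, 0)
  dim(act2) <- c(d[1L], d[2L], d[3L], m)
  r <- minimodel@readout
  pooledWxy <- pooledChannels(act2, r)
  z <- as.vector(pooledWxy %*% r@wc) + r@offset
  rate <- elu(z) + 1
  gap <- function(x) {
    dd <- dim(x)
    mat <- matrix(x, nrow = dd[1L] * dd[2L])           # (H*W) x (N*C)
    avg <- colMeans(mat)
    matrix(avg, nrow = dd[3L], ncol = dd[4L])
  }
  out <- c(
    conv1 = fecvOverUnits(sharedStages$conv1Gap, category),
    pool = fecvOverUnits(sharedStages$pooled1Gap, category),
    conv2_spatial = fecvOverUnits(gap(s2), category),
    conv2_mix_relu = fecvOverUnits(gap(act2), category),
    pooled_wxy = fecvOverUnits(pooledWxy, category),
    readout = suppressMessages(as.numeric(fecvPairwise(rate, category))))
  out
}

#' Precompute the shared conv1 stages on a texture set
#'
#' The conv1 and pooling stages (and their globally averaged summaries) are
#' identical for every minimodel sharing a conv1 bank; computing them once
#' makes population-level stage-wise analyses affordable.
#'
#' @param conv1 the shared 1-layer [ConvCore-class].
#' @param textures a [TextureStimulusSet-class] (or image array).
#' @return list with `pooled1` (feature array) and the globally averaged
#'   `conv1Gap`, `pooled1Gap` matrices.
#' @export
precomputeConv1Stages <- function(conv1, textures, chunk = 128L) {
  imgs <- if (is(textures, "StimulusSet")) images(textures) else textures
  layer <- conv1@layers[[1L]]
  d <- dim(imgs)
  n <- d[3L]
  C <- dim(layer$kernels)[3L]
  gap <- function(arr) {
    dd <- dim(arr)
    matrix(colMeans(matrix(arr, nrow = dd[1L] * dd[2L])),
           nrow = dd[3L], ncol = dd[4L])
  }
  pooled1 <- array(0, c(d[1L] %/% 2L, d[2L] %/% 2L, n, C))
  conv1Gap <- matrix(0, n, C)
  for (s in seq(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    x <- cc_conv1_forward(imgs[, , ix, drop = FALSE], layer$kernels)
    x <- applyBatchNorm(x, layer, mode = "eval")
    a <- pmax(x, 0) * 1
    dim(a) <- dim(x)
    conv1Gap[ix, ] <- gap(a)
    pooled1[, , ix, ] <- cc_maxpool2(a)$y
  }
  list(pooled1 = pooled1, conv1Gap = conv1Gap, pooled1Gap = gap(pooled1))
}

#' Compare category variance of model neurons and "recorded" neurons
#'
#' Simulates each minimodel's responses to the texture presentations with
#' Poisson noise whose single gain is calibrated ([calibrateNoiseToFEV()])
#' so the model population's mean FEV on the repeated test exemplars matches
#' the recorded population's, then computes the pairwise FECV of both sides
#' on the same trial structure and their Pearson correlation.
#'
#' @param minimodels list of fitted [Minimodel-class] (or
#'   [GroundTruthNeuron-class]) objects.
#' @param responseSet recorded (or simulated-recorded) [ResponseSet-class]
#'   on `textures`.
#' @param textures the [TextureStimulusSet-class] shown.
#' @param seed integer seed for the Poisson draws.
#' @param conv1Feats optional precomputed conv1 features.
#' @return data.frame with per-neuron `fecvNeuron`, `fecvModel`; the Pearson
#'   correlation is in attribute `"correlation"`, the calibrated gain in
#'   `"gain"`.
#' @export
compareModelNeuronFECV <- function(minimodels, responseSet, textures,
                                   seed = 1L, conv1Feats = NULL) {
  if (is.null(conv1Feats))
    conv1Feats <- conv1Features(minimodels[[1L]]@conv1, textures)
  nI <- dim(conv1Feats)[3L]
  rates <- vapply(minimodels, function(m) minimodelPredict(m, conv1Feats),
                  numeric(nI))
  pres <- presentationMap(responseSet)
  catTrial <- categoryIndex(responseSet)
  stopIfNot(!is.null(catTrial), "responseSet lacks category annotations")
  # recorded mean FEV on repeated test exemplars
  split <- splitLabels(textures)
  testImgs <- which(split == "test")
  Yrec <- responses(responseSet)
  fevRec <- vapply(seq_len(ncol(Yrec)), function(i)
    suppressWarnings(fev(repeatMatrix(responseSet, i, testImgs))), 0)
  target <- mean(fevRec, na.rm = TRUE)
  gain <- calibrateNoiseToFEV(rates[testImgs, , drop = FALSE],
                              targetMeanFEV = min(max(target, 1e-4), 0.999))
  expected <- gain * rates[pres$image, , drop = FALSE]
  sim <- withSeed(seed, matrix(rpois(length(expected), expected),
                               nrow(expected), ncol(expected)))
  fecvOf <- function(Y) vapply(seq_len(ncol(Y)), function(i) {
    suppressMessages(as.numeric(fecvPairwise(Y[, i], catTrial)))
  }, 0)
  out <- data.frame(neuron = seq_along(minimodels),
                    fecvNeuron = fecvOf(Yrec), fecvModel = fecvOf(sim))
  structure(out,
            correlation = stats::cor(out$fecvNeuron, out$fecvModel),
            gain = as.numeric(gain))
}

#' Top stimuli of a minimodel, masked by its readout
#'
#' Ranks stimuli by model output and masks the top `nTop` with an elliptical
#' window centered at the peak of the readout, with semi-axes given by half
#' the half-max widths of `wx`/`wy` dilated by the conv1 kernel size (25 px),
#' every pixel inside weighted by the outer product of the readout vectors
#' (upsampled to image resolution by nearest neighbor). With a flat readout
#' the mask falls back to the full image with a warning. Optionally ranks
#' stimuli per conv2 channel instead.
#'
#' @param minimodel a fitted [Minimodel-class].
#' @param stimuli a [StimulusSet-class] or image array with >= `nTop` images.
#' @param nTop number of top stimuli.
#' @param perChannel if `TRUE`, return the top `nTopChannel` stimulus indices
#'   per conv2 channel (ranked by pooled activation) instead of masked
#'   images.
#' @param nTopChannel top stimuli per channel.
#' @param dilatePx mask dilation in image px (the conv1 kernel size).
#' @return for the default mode, a list with `indices` (sorted by strictly
#'   non-increasing model output), `output`, `mask` and `maskedImages`; for
#'   `perChannel`, a list of index vectors ordered by `wc`.
#' @export
maskedTopStimuli <- function(minimodel, stimuli, nTop = 16L,
                             perChannel = FALSE, nTopChannel = 8L,
                             dilatePx = 25) {
  imgs <- if (is(stimuli, "StimulusSet")) images(stimuli) else stimuli
  n <- dim(imgs)[3L]
  stopIfNot(n >= nTop, "need at least nTop stimuli")
  a0 <- conv1Features(minimodel@conv1, imgs)
  if (perChannel) {
    pooled <- minimodelPooled(minimodel, a0)
    ordCh <- order(minimodel@readout@wc, decreasing = TRUE)
    return(lapply(stats::setNames(ordCh, paste0("channel", ordCh)),
                  function(m)
                    order(pooled[, m], decreasing = TRUE)[seq_len(nTopChannel)]))
  }
  out <- minimodelPredict(minimodel, a0)
  ord <- order(out, decreasing = TRUE)[seq_len(nTop)]
  H <- dim(imgs)[1L]
  W <- dim(imgs)[2L]
  up <- function(w, len) rep(w, each = ceiling(len / length(w)))[seq_len(len)]
  wyU <- up(minimodel@readout@wy, H)
  wxU <- up(minimodel@readout@wx, W)
  if (max(wxU) <= 0 || max(wyU) <= 0) {
    warning("flat readout: mask undefined, using the full image")
    mask <- matrix(1, H, W)
  } else {
    sy <- smoothGaussian1d(wyU, 3)
    sx <- smoothGaussian1d(wxU, 3)
    cy <- which.max(sy)
    cx <- which.max(sx)
    ry <- (fwhmWidth(sy) + dilatePx) / 2
    rx <- (fwhmWidth(sx) + dilatePx) / 2
    inside <- outer(((seq_len(H) - cy) / ry)^2,
                    ((seq_len(W) - cx) / rx)^2, `+`) <= 1
    wgt <- outer(wyU / max(wyU), wxU / max(wxU))
    mask <- ifelse(inside, wgt, 0)
  }
  masked <- array(0, c(H, W, nTop))
  for (i in seq_len(nTop)) masked[, , i] <- imgs[, , ord[i]] * mask
  list(indices = ord, output = out[ord], mask = mask, maskedImages = masked)
}
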