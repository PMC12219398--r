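# 2-D Gaussian-envelope random kernel, unit norm
smoothRandomKernel <- function(k, envSigma = k / 3.5) {
  u <- seq_len(k) - (k + 1) / 2
  env <- exp(-outer(u^2, u^2, `+`) / (2 * envSigma^2))
  g <- matrix(rnorm(k * k), k, k) * env
  g / sqrt(sum(g^2))
}

discretizedGaussian <- function(n, center, sigma) {
  w <- exp(-0.5 * ((seq_len(n) - center) / sigma)^2)
  w / sum(w)
}

#' Build a population of ground-truth minimodel neurons
#'
#' Each neuron is a fully specified [GroundTruthNeuron-class]: random smooth
#' depthwise conv2 kernels over the shared conv1 bank, a sparse signed 1x1
#' mix into `channelsPerNeuron` output channels, batch-norm statistics
#' calibrated on the supplied stimuli, a Gaussian factorized readout at a
#' random center with mixed-sign channel weights, and a gain scaled so the
#' mean expected response on the calibration stimuli is `targetMeanRate`
#' events per presentation. Neuron parameters depend only on `(seed, index)`.
#'
#' @param conv1Bank shared 1-layer [ConvCore-class] (see [makeConv1Bank()]).
#' @param stimuli calibration [StimulusSet-class]; batch-norm statistics,
#'   readout scaling and gains are computed from its images.
#' @param nNeurons number of neurons.
#' @param channelsPerNeuron number of active conv2 channels per neuron
#'   (<= 64).
#' @param poolingSigmaPx readout Gaussian width in feature-map samples; a
#'   scalar, or a range `c(lo, hi)` sampled uniformly per neuron.
#' @param sourceRange optional range for the number of distinct conv1
#'   channels a neuron's conv2 channels may draw on (sampled per neuron,
#'   log-uniformly); `NULL` (default) lets every channel draw from the full
#'   bank. A narrow low range builds neurons with redundant inputs.
#' @param seed integer seed.
#' @param targetMeanRate target mean expected event count per presentation
#'   (default 2, which puts the Poisson-noise FEV of typical neurons near
#'   0.5, the regime of reliable cortical responses).
#' @param excitatoryFraction probability that a channel weight is positive.
#' @param conv1Feats optional precomputed [conv1Features()] of `stimuli`.
#' @return list of [GroundTruthNeuron-class] objects.
#' @export
makeGroundTruthPopulation <- function(conv1Bank, stimuli, nNeurons,
                                      channelsPerNeuron = 4L,
                                      poolingSigmaPx = 6,
                                      sourceRange = NULL,
                                      seed = 1L, targetMeanRate = 2,
                                      excitatoryFraction = 0.7,
                                      conv1Feats = NULL) {
  stopIfNot(channelsPerNeuron >= 1L && channelsPerNeuron <= 64L,
            "channelsPerNeuron must be in 1..64")
  a0 <- if (is.null(conv1Feats)) conv1Features(conv1Bank, stimuli) else conv1Feats
  d <- dim(a0)
  H <- d[1L]; W <- d[2L]; C1 <- d[4L]
  k2 <- 9L
  lapply(seq_len(nNeurons), function(i) {
    withSeed(seed + 7919L * i, {
      M <- as.integer(channelsPerNeuron)
      spatial <- array(0, c(k2, k2, C1))
      for (c in seq_len(C1)) spatial[, , c] <- smoothRandomKernel(k2)
      # neuron-specific source pool: how many distinct conv1 channels its
      # conv2 channels can draw on (full bank unless a range is given)
      nSrc <- if (is.null(sourceRange)) C1 else
        max(1L, min(C1, round(exp(runif(1, log(sourceRange[1L]),
                                        log(sourceRange[2L]))))))
      sources <- if (nSrc == C1) seq_len(C1) else sample(C1, nSrc)
      mix <- matrix(0, C1, M)
      for (m in seq_len(M)) {
        picks <- if (nSrc == 1L) sources
                 else sample(sources, min(sample(2:3, 1L), nSrc))
        mix[picks, m] <- rnorm(length(picks))
        mix[, m] <- mix[, m] / sqrt(sum(mix[, m]^2))
      }
      sigma <- if (length(poolingSigmaPx) == 2L)
        runif(1, poolingSigmaPx[1L], poolingSigmaPx[2L]) else poolingSigmaPx
      wy <- discretizedGaussian(H, runif(1, 0.3 * H, 0.7 * H), sigma)
      wx <- discretizedGaussian(W, runif(1, 0.3 * W, 0.7 * W), sigma)
      signs <- ifelse(runif(M) < excitatoryFraction, 1, -1)
      wc <- signs * abs(rnorm(M, 1, 0.3))
      # calibrate batch norm on the pre-normalization conv2 activations
      s2 <- cc_dwconv_forward(a0, spatial)
      u <- matrix(s2, ncol = C1) %*% mix
      bnMean <- colMeans(u)
      bnVar <- pmax(colMeans(u^2) - bnMean^2, 1e-12)
      beta <- runif(M, 0.1, 0.5)
      mm <- Minimodel(conv1 = conv1Bank, conv2Spatial = spatial,
                      conv2Mix = mix, bnGamma = rep(1, M), bnBeta = beta,
                      bnMean = bnMean, bnVar = bnVar,
                      readout = FactorizedReadout(wx, wy, wc, 0))
      # scale the channel weights so the readout has unit variance, then
      # center it slightly positive so rates spread over a realistic range
      z0 <- mm_forward(a0, spatial, mix, mm@bnGamma, mm@bnBeta, bnMean, bnVar,
                       wx, wy, wc, 0, bnEps, FALSE)$z
      zsd <- max(stats::sd(z0), 1e-12)
      mm@readout@wc <- wc / zsd
      mm@readout@offset <- 0.3 - mean(z0) / zsd
      z <- (z0 - mean(z0)) / zsd + 0.3
      rate <- elu(z) + 1
      gain <- targetMeanRate / mean(rate)
      new("GroundTruthNeuron", mm, gain = gain)
    })
  })
}

# presentation scaffold for a stimulus set: train/val once, test J times
presentationTable <- function(stimuli) {
  split <- splitLabels(stimuli)
  once <- which(split != "test")
  test <- which(split == "test")
  J <- testRepeats(stimuli)
  img <- c(once, rep(test, times = J))
  rep_ <- c(rep(1L, length(once)), rep(seq_len(J), each = length(test)))
  data.frame(image = img, rep = rep_)
}

buildResponseSet <- function(stimuli, resp, pres) {
  cat_ <- if (is(stimuli, "TextureStimulusSet"))
    categoryIndex(stimuli)[pres$image] else integer(0)
  new("ResponseSet", responses = resp, presentation = pres,
      category = as.integer(cat_))
}

#' @describeIn simulateResponses responses of ground-truth minimodel neurons.
#' @param noise `"poisson"` for Poisson counts, `"none"` for the expected
#'   rates (noiseless limit).
#' @param conv1Feats optional precomputed conv1 features for the stimuli.
#' @export
setMethod("simulateResponses", "list",
  function(object, stimuli, seed = 1L, noise = c("poisson", "none"),
           conv1Feats = NULL) {
    noise <- match.arg(noise)
    stopIfNot(all(vapply(object, is, TRUE, "GroundTruthNeuron")),
              "object must be a list of GroundTruthNeuron")
    if (is.null(conv1Feats))
      conv1Feats <- conv1Features(object[[1L]]@conv1, stimuli)
    rates <- vapply(object, function(nn)
      nn@gain * minimodelPredict(nn, conv1Feats), numeric(dim(conv1Feats)[3L]))
    pres <- presentationTable(stimuli)
    expected <- rates[pres$image, , drop = FALSE]
    resp <- if (noise == "poisson") {
      withSeed(seed, matrix(rpois(length(expected), expected),
                            nrow(expected), ncol(expected)))
    } else expected
    buildResponseSet(stimuli, resp, pres)
  })

#' @describeIn simulateResponses responses of a population model (rates taken
#'   as expected event counts scaled by `gain`).
#' @param gain scalar rate multiplier for population models.
#' @export
setMethod("simulateResponses", "PopulationModel",
  function(object, stimuli, seed = 1L, noise = c("poisson", "none"),
           gain = 1) {
    noise <- match.arg(noise)
    feats <- coreForward(object@core, stimuli)
    rates <- gain * vapply(object@readouts,
                           function(r) readoutForward(feats, r),
                           numeric(dim(feats)[3L]))
    pres <- presentationTable(stimuli)
    expected <- rates[pres$image, , drop = FALSE]
    resp <- if (noise == "poisson") {
      withSeed(seed, matrix(rpois(length(expected), expected),
                            nrow(expected), ncol(expected)))
    } else expected
    buildResponseSet(stimuli, resp, pres)
  })

#' Calibrate a Poisson-noise gain to a target mean FEV
#'
#' For Poisson observation noise the expected FEV of a neuron with per-image
#' rates `g * r_i` is `g * Var_i[r] / (g * Var_i[r] + mean_i[r])`, which is
#' monotonically increasing in the gain `g`. The calibration finds, by
#' bisection on `log(g)`, the gain at which the mean expected FEV across
#' neurons matches the target within the tolerance (used to match model-
#' neuron noise to recorded noise before comparing category variances).
#'
#' @param modelRates matrix `(n_images, n_neurons)` (or vector) of per-image
#'   expected rates at gain 1.
#' @param targetMeanFEV target mean FEV, in (0, 1).
#' @param tolerance acceptable |achieved - target| (default 0.001, i.e.,
#'   within 0.1%).
#' @param gainBounds search interval for the gain.
#' @return the calibrated gain, with attributes `achievedFEV` and `flagged`
#'   (TRUE when the target is unreachable within the bounds, in which case
#'   the best achievable endpoint is returned with a warning).
#' @export
calibrateNoiseToFEV <- function(modelRates, targetMeanFEV, tolerance = 0.001,
                                gainBounds = c(1e-6, 1e6)) {
  stopIfNot(targetMeanFEV > 0 && targetMeanFEV < 1,
            "targetMeanFEV must be in (0, 1)")
  r <- as.matrix(modelRates)
  s2 <- apply(r, 2L, stats::var)
  m <- colMeans(r)
  keep <- s2 > 0 & m > 0
  stopIfNot(any(keep), "all neurons have degenerate rates")
  meanFev <- function(g) mean(g * s2[keep] / (g * s2[keep] + m[keep]))
  lo <- log(gainBounds[1L])
  hi <- log(gainBounds[2L])
  fLo <- meanFev(exp(lo))
  fHi <- meanFev(exp(hi))
  if (targetMeanFEV < fLo - tolerance || targetMeanFEV > fHi + tolerance) {
    best <- if (abs(fLo - targetMeanFEV) < abs(fHi - targetMeanFEV))
      exp(lo) else exp(hi)
    warning(sprintf(
      "target FEV %.3f unreachable in gain bounds (achievable %.3f..%.3f)",
      targetMeanFEV, fLo, fHi))
    return(structure(best, achievedFEV = meanFev(best), flagged = TRUE))
  }
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f <- meanFev(exp(mid))
    if (abs(f - targetMeanFEV) <= tolerance * 0.5) break
    if (f < targetMeanFEV) lo <- mid else hi <- mid
  }
  g <- exp((lo + hi) / 2)
  structure(g, achievedFEV = meanFev(g), flagged = FALSE)
}
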