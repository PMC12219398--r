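# Gabor filter on an (height x width) pixel grid, centered at (cy, cx).
# Parameterization: the Gaussian envelope has sigma_major = alpha px along
# the carrier axis and sigma_minor = alpha / beta px; the carrier frequency
# f is in cycles per alpha (so the wavelength is alpha / f px), which keeps
# the printed f grid (0.1 .. 2) inside the representable band at every size.
# Filters are mean-subtracted so they have exactly zero DC response.
gaborKernel <- function(height, width, cy, cx, f, theta, psi, alpha, beta) {
  y <- seq_len(height) - cy
  x <- seq_len(width) - cx
  xr <- outer(rep(1, height), x) * cos(theta) + outer(y, rep(1, width)) * sin(theta)
  yr <- -outer(rep(1, height), x) * sin(theta) + outer(y, rep(1, width)) * cos(theta)
  env <- exp(-(xr^2 / (2 * alpha^2) + yr^2 / (2 * (alpha / beta)^2)))
  g <- env * cos(2 * pi * f * xr / alpha + psi)
  g - mean(g)
}

#' Build a bank of Gabor filters over parameter grids
#'
#' The default grids are spatial frequency f in \{0.1, 0.25, 0.5, 1, 2\}
#' (cycles per envelope size alpha), orientation theta in \{0, pi/8, pi/4,
#' 3pi/8\}, phase psi in \{0, pi/4, ..., 7pi/4\}, size alpha in \{0.75, 1.25,
#' 1.5, 2.5, 3.5, 4.5, 5.5\} and eccentricity beta in \{1, 1.5, 2\} (3,360
#' parameter tuples), replicated over a configurable grid of filter centers.
#' All filters are zero-mean.
#'
#' @param height,width image size in px the filters act on.
#' @param centers matrix with columns `(cy, cx)` of filter centers; default
#'   is the single image center.
#' @param freqs,thetas,psis,alphas,betas parameter grids.
#' @param alphaScale multiply the size grid by this factor (sizes are in px
#'   at the working resolution).
#' @return list with `filters` (a `height*width x n` matrix, one filter per
#'   column) and `params` (a data.frame of the parameter tuples, including a
#'   `quadrature` column giving the index of the +90-degree-phase partner).
#' @export
buildGaborBank <- function(height, width, centers = NULL,
                           freqs = c(0.1, 0.25, 0.5, 1, 2),
                           thetas = c(0, pi / 8, pi / 4, 3 * pi / 8),
                           psis = seq(0, 7) * pi / 4,
                           alphas = c(0.75, 1.25, 1.5, 2.5, 3.5, 4.5, 5.5),
                           betas = c(1, 1.5, 2),
                           alphaScale = 1) {
  if (is.null(centers))
    centers <- matrix(c((height + 1) / 2, (width + 1) / 2), 1L)
  grid <- expand.grid(psi = psis, f = freqs, theta = thetas,
                      alpha = alphas * alphaScale, beta = betas,
                      center = seq_len(nrow(centers)))
  n <- nrow(grid)
  filters <- matrix(0, height * width, n)
  for (i in seq_len(n)) {
    g <- grid[i, ]
    filters[, i] <- as.vector(gaborKernel(height, width,
                                          centers[g$center, 1L],
                                          centers[g$center, 2L],
                                          g$f, g$theta, g$psi, g$alpha,
                                          g$beta))
  }
  # quadrature partner: same tuple with psi shifted by pi/2
  key <- function(psi) paste(round(psi %% (2 * pi), 10), grid$f, grid$theta,
                             grid$alpha, grid$beta, grid$center)
  quad <- match(key(grid$psi + pi / 2), key(grid$psi))
  grid$quadrature <- quad
  grid$cy <- centers[grid$center, 1L]
  grid$cx <- centers[grid$center, 2L]
  list(filters = filters, params = grid, height = height, width = width)
}

#' Simple-cell response: rectified projection onto a filter
#'
#' @param filter numeric filter (vector or matrix).
#' @param image image with the same number of pixels.
#' @return `max(0, <image, filter>)`.
#' @export
simpleResponse <- function(filter, image) {
  max(0, sum(as.vector(filter) * as.vector(image)))
}

#' Complex-cell (energy) response from a quadrature pair
#'
#' Root-mean-square of the two unrectified projections onto a filter and its
#' 90-degree-phase-shifted partner; phase-invariant for gratings matched to
#' the filter.
#'
#' @param filter,filterQuad the quadrature filter pair.
#' @param image image with the same number of pixels.
#' @return energy response.
#' @export
complexResponse <- function(filter, filterQuad, image) {
  r1 <- sum(as.vector(filter) * as.vector(image))
  r2 <- sum(as.vector(filterQuad) * as.vector(image))
  sqrt((r1^2 + r2^2) / 2)
}

#' Fit the simple/complex Gabor model to one neuron
#'
#' For every filter in the bank, the neuron's responses on the train+val
#' images are regressed (least squares, with intercept) on the filter's
#' simple (rectified) and complex (energy) responses with weights `C1`, `C2`;
#' the filter with the lowest residual error is selected. The neuron is
#' classified as complex when `C2 / (C1 + C2) > 0.5` and simple otherwise.
#' Filters whose regressors are degenerate on the fitting images are
#' skipped.
#'
#' @param y per-image responses used for fitting (train+val images,
#'   trial-averaged).
#' @param imgs `(H, W, N)` array (or [StimulusSet-class]) aligned with `y`;
#'   images are used at this resolution (downsample beforehand if needed).
#' @param bank a [buildGaborBank()] bank matching the image size.
#' @param testRep optional `I x J` repeat matrix of test responses and
#'   `testImgs` the matching images; when given, the test FEVE of the
#'   selected filter is reported.
#' @param testImgs see `testRep`.
#' @return list with `filter` (index), `C1`, `C2`, `ratio`, `class`
#'   ("simple"/"complex"), `trainR2`, and `testFEVE` (NA unless test data
#'   given).
#' @export
fitGaborNeuron <- function(y, imgs, bank, testRep = NULL, testImgs = NULL) {
  if (is(imgs, "StimulusSet")) imgs <- images(imgs)
  X <- matrix(imgs, ncol = dim(imgs)[3L])
  U <- crossprod(bank$filters, X)              # nfilt x nimg, unrectified
  simple <- pmax(U, 0)
  quad <- bank$params$quadrature
  cmplx <- sqrt((U^2 + U[quad, , drop = FALSE]^2) / 2)
  n <- nrow(U)
  bestRss <- Inf
  best <- NULL
  for (fIdx in seq_len(n)) {
    s <- simple[fIdx, ]
    c2 <- cmplx[fIdx, ]
    if (stats::sd(s) == 0 || stats::sd(c2) == 0) next
    fit <- stats::lsfit(cbind(simple = s, complex = c2), y)
    rss <- sum(fit$residuals^2)
    if (is.finite(rss) && rss < bestRss) {
      bestRss <- rss
      best <- list(filter = fIdx, C1 = unname(fit$coefficients["simple"]),
                   C2 = unname(fit$coefficients["complex"]),
                   intercept = unname(fit$coefficients["Intercept"]))
    }
  }
  if (is.null(best)) stop("all filters degenerate on these images",
                          call. = FALSE)
  best$ratio <- best$C2 / (best$C1 + best$C2)
  best$class <- if (best$ratio > 0.5) "complex" else "simple"
  best$trainR2 <- 1 - bestRss / sum((y - mean(y))^2)
  best$testFEVE <- NA_real_
  if (!is.null(testRep) && !is.null(testImgs)) {
    if (is(testImgs, "StimulusSet")) testImgs <- images(testImgs)
    Xt <- matrix(testImgs, ncol = dim(testImgs)[3L])
    ut <- as.vector(crossprod(bank$filters[, best$filter], Xt))
    uq <- as.vector(crossprod(bank$filters[, quad[best$filter]], Xt))
    pred <- best$intercept + best$C1 * pmax(ut, 0) +
      best$C2 * sqrt((ut^2 + uq^2) / 2)
    best$testFEVE <- feve(testRep, pred)
  }
  best
}

#' Fit the linear-nonlinear (LN) baseline
#'
#' The LN model is the standard core with the nonlinear activations removed
#' (identity) and the max pool replaced by an average pool, trained with the
#' usual procedure; its pre-output prediction is linear in the stimulus.
#'
#' @param stimuli,responseSet,config as in [trainPopulation()].
#' @param channels per-layer channel counts (default 16-320).
#' @param nLayers core depth.
#' @param kernelSizes per-layer kernel sizes.
#' @return a [PopulationModel-class] in LN mode.
#' @export
lnModelFit <- function(stimuli, responseSet, config = trainConfig(),
                       channels = c(16L, 320L), nLayers = 2L,
                       kernelSizes = c(25L, 9L, 5L, 5L)) {
  cfg <- coreConfig(nLayers = nLayers, channels = channels,
                    kernelSizes = kernelSizes, activation = "identity",
                    poolType = "avg")
  trainPopulation(cfg, stimuli, responseSet, config)
}
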