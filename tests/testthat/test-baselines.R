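test_that("the printed parameter grids multiply to 3,360 tuples", {
  # grid product of the default frequency/orientation/phase/size/eccentricity
  # grids, per filter center
  bank <- buildGaborBank(16, 16)
  expect_identical(nrow(bank$params), 5L * 4L * 8L * 7L * 3L)
  expect_identical(ncol(bank$filters), 3360L)
})

test_that("gabor filters are zero-mean with quadrature partners", {
  gf <- gaborFixture()
  expect_lt(max(abs(colMeans(gf$bank$filters))), 1e-8)
  q <- gf$bank$params$quadrature
  expect_false(any(is.na(q)))
  # psi and psi+pi filters are negatives of each other (cosine antiperiod;
  # the Gaussian envelope is phase independent)
  p <- gf$bank$params
  i <- which(p$theta == 0 & p$psi == 0)[1L]
  j <- which(p$theta == 0 & p$psi == pi & p$f == p$f[i] &
             p$alpha == p$alpha[i] & p$beta == p$beta[i] &
             p$center == p$center[i])[1L]
  expect_equal(gf$bank$filters[, i], -gf$bank$filters[, j],
               tolerance = 1e-10)
})

test_that("simple responses rectify the filter projection", {
  gf <- gaborFixture()
  f <- matrix(gf$bank$filters[, 10], gf$h, gf$w)
  expect_equal(simpleResponse(f, f), sum(f^2))
  expect_equal(simpleResponse(f, -f), 0)
  # orthogonal image
  img <- matrix(gf$bank$filters[, 10], gf$h, gf$w)
  img <- img - f * sum(img * f) / sum(f^2)
  expect_lt(abs(simpleResponse(f, img)), 1e-8)
})

test_that("the energy model is phase invariant on matched gratings", {
  gf <- gaborFixture()
  p <- gf$bank$params[500, ]
  yy <- outer(1:gf$h, rep(1, gf$w))
  xx <- outer(rep(1, gf$h), 1:gf$w)
  xr <- (xx - p$cx) * cos(p$theta) + (yy - p$cy) * sin(p$theta)
  resp <- sapply(seq(0, 2 * pi, length.out = 25), function(ph) {
    g <- cos(2 * pi * p$f * xr / p$alpha + ph)
    complexResponse(gf$bank$filters[, 500],
                    gf$bank$filters[, p$quadrature], g)
  })
  expect_lt((max(resp) - min(resp)) / mean(resp), 0.05)
  expect_equal(complexResponse(gf$bank$filters[, 500],
                               gf$bank$filters[, p$quadrature],
                               matrix(0, gf$h, gf$w)), 0)
  # sign flip of the image leaves the energy unchanged
  img <- withSeed(72, matrix(rnorm(gf$h * gf$w), gf$h, gf$w))
  expect_equal(complexResponse(gf$bank$filters[, 500],
                               gf$bank$filters[, p$quadrature], img),
               complexResponse(gf$bank$filters[, 500],
                               gf$bank$filters[, p$quadrature], -img))
})

test_that("planted simple and complex neurons are classified correctly", {
  gf <- gaborFixture()
  X <- matrix(images(gf$stim), ncol = nImages(gf$stim))
  fitIdx <- which(splitLabels(gf$stim) != "test")
  ids <- withSeed(73, sample(ncol(gf$bank$filters), 20))
  cls <- rep(c("simple", "complex"), 10)
  for (i in seq_along(ids)) {
    fid <- ids[i]
    u <- as.vector(crossprod(gf$bank$filters[, fid], X))
    uq <- as.vector(crossprod(
      gf$bank$filters[, gf$bank$params$quadrature[fid]], X))
    y <- if (cls[i] == "simple") pmax(u, 0) else sqrt((u^2 + uq^2) / 2)
    fit <- fitGaborNeuron(y[fitIdx], images(gf$stim)[, , fitIdx], gf$bank)
    expect_identical(fit$class, cls[i])
    if (cls[i] == "complex") expect_gt(fit$ratio, 0.9)
  }
})

test_that("a constant-regressor filter is skipped, not fitted", {
  gf <- gaborFixture()
  # all-zero images make every filter degenerate
  zero <- array(0, c(gf$h, gf$w, 10))
  expect_error(fitGaborNeuron(rep(1, 10), zero, gf$bank), "degenerate")
})

test_that("the LN model prediction is linear before the output map", {
  tw <- tinyWorld()
  cfg <- coreConfig(nLayers = 2, channels = c(4L, 6L),
                    kernelSizes = c(13L, 5L), activation = "identity",
                    poolType = "avg")
  core <- newConvCore(cfg, seed = 75)
  ro <- withSeed(76, FactorizedReadout(runif(24), runif(16), rnorm(6), 0))
  x <- images(tw$stim)[, , 1, drop = FALSE]
  y <- images(tw$stim)[, , 2, drop = FALSE]
  zf <- function(img) readoutForward(coreForward(core, img), ro, rate = FALSE)
  z0 <- zf(array(0, dim(x)))
  lhs <- zf(array(0.6 * x - 1.1 * y, dim(x))) - z0
  rhs <- 0.6 * (zf(x) - z0) - 1.1 * (zf(y) - z0)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("lnModelFit trains an identity-activation, average-pooling core", {
  tw <- tinyWorld()
  rs <- simulateResponses(tw$neurons, tw$stim, seed = 77, noise = "none",
                          conv1Feats = tw$feats)
  fit <- lnModelFit(tw$stim, rs,
                    config = trainConfig(scheduleScale = 0.02,
                                         batchSize = 16L, seed = 78),
                    channels = c(4L, 6L), nLayers = 2L,
                    kernelSizes = c(13L, 5L))
  expect_identical(fit@core@config$activation, "identity")
  expect_identical(fit@core@config$poolType, "avg")
  # superposition before the output map
  imgs <- images(tw$stim)
  x <- imgs[, , 1, drop = FALSE]
  y <- imgs[, , 2, drop = FALSE]
  zf <- function(img) readoutForward(coreForward(fit@core, img),
                                     fit@readouts[[1L]], rate = FALSE)
  z0 <- zf(array(0, dim(x)))
  expect_equal(zf(array(0.5 * x + 2 * y, dim(x))) - z0,
               0.5 * (zf(x) - z0) + 2 * (zf(y) - z0), tolerance = 1e-5)
})
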