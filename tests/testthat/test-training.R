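test_that("poisson loss closed-form values and gradient", {
  expect_equal(poissonLoss(1, 1), 1)
  expect_equal(poissonLoss(exp(1), 0), exp(1))
  expect_error(poissonLoss(c(1, -1), c(0, 0)), "positive")
  # gradient in the rate is (1 - response/rate), zero at rate = response
  rate <- 2.5; resp <- 1.5
  eps <- 1e-6
  num <- (poissonLoss(rate + eps, resp) - poissonLoss(rate - eps, resp)) /
    (2 * eps)
  expect_equal(num, 1 - resp / rate, tolerance = 1e-6)
  num0 <- (poissonLoss(resp + eps, resp) - poissonLoss(resp - eps, resp)) /
    (2 * eps)
  expect_lt(abs(num0), 1e-6)
})

test_that("Hoyer-Square closed forms and finite-difference gradient", {
  expect_equal(hoyerSquare(c(0, 0, 5, 0)), 1)
  for (k in c(2, 7, 13))
    expect_equal(hoyerSquare(rep(0.3, k)), k, tolerance = 1e-12)
  expect_equal(hoyerSquare(numeric(4)), 0)
  # scale invariance
  w <- c(0.5, -1, 2, 0, 0.1)
  expect_equal(hoyerSquare(w), hoyerSquare(3.7 * w), tolerance = 1e-12)
  g <- miniV1:::hoyerSquareGrad(w)
  eps <- 1e-7
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(g[i], (hoyerSquare(wp) - hoyerSquare(wm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("the training schedule keeps the divide-by-3 learning-rate ladder", {
  cfg <- trainConfig()
  expect_equal(cfg$schedule$epochs, c(100, 30, 30, 30))
  expect_equal(cfg$schedule$lr, 1e-3 / c(1, 3, 9, 27))
  red <- trainConfig(scheduleScale = 0.1)
  expect_equal(red$schedule$epochs, c(10, 3, 3, 3))
  expect_equal(red$schedule$lr, 1e-3 / c(1, 3, 9, 27))
  expect_true(all(diff(red$schedule$lr) < 0))
})

test_that("the fused minimodel step matches finite-difference gradients", {
  withSeed(41, {
    H <- 6L; W <- 8L; B <- 5L; C1 <- 3L; M <- 4L; k <- 3L
    a0 <- array(rnorm(H * W * B * C1), c(H, W, B, C1))
    resp <- rpois(B, 2)
    par <- list(k2 = array(rnorm(k * k * C1, 0, 0.3), c(k, k, C1)),
                mix = matrix(rnorm(C1 * M, 0, 0.4), C1, M),
                gamma = runif(M, 0.5, 1.5), beta = rnorm(M, 0, 0.2),
                wx = runif(W), wy = runif(H), wc = rnorm(M, 0, 0.5),
                offset = 0.1)
    st <- miniV1:::mm_step(a0, resp, par$k2, par$mix, par$gamma, par$beta,
                           par$wx, par$wy, par$wc, par$offset, 1e-5)
    lossAt <- function(p)
      miniV1:::mm_step(a0, resp, p$k2, p$mix, p$gamma, p$beta, p$wx, p$wy,
                       p$wc, p$offset, 1e-5)$loss
    eps <- 1e-6
    for (nm in names(par)) {
      g <- st[[paste0("d", nm)]]
      num <- par[[nm]] * 0
      for (i in seq_along(par[[nm]])) {
        p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
        num[i] <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
      }
      expect_equal(as.numeric(g), as.numeric(num), tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  })
})

test_that("population training recovers a planted shared-core model", {
  cfg <- coreConfig(nLayers = 2, channels = c(8L, 16L),
                    kernelSizes = c(13L, 7L))
  stim <- generateNaturalImages(550, 36, 52, seed = 61, nTest = 50)
  core <- calibrateCore(newConvCore(cfg, seed = 62), stim)
  readouts <- withSeed(63, lapply(1:5, function(i) {
    wy <- exp(-0.5 * ((1:18 - runif(1, 6, 12)) / 3)^2)
    wx <- exp(-0.5 * ((1:26 - runif(1, 8, 18)) / 3)^2)
    FactorizedReadout(wx / sum(wx), wy / sum(wy), rnorm(16, 0, 0.5), 0.2)
  }))
  gt <- new("PopulationModel", core = core, readouts = readouts, log = list())
  rs <- simulateResponses(gt, stim, seed = 64, noise = "none")
  fit <- trainPopulation(cfg, stim, rs,
                         trainConfig(scheduleScale = 0.1, batchSize = 16L,
                                     seed = 65, checkInvariants = TRUE))
  expect_gt(fit@log$bestValScore, 0.8)
  # the selected snapshot is the argmax over epochs (>= initialization and
  # >= the final epoch)
  expect_gte(fit@log$bestValScore, tail(fit@log$epochs$valScore, 1))
  # wx/wy non-negative in the returned model
  for (ro in fit@readouts) {
    expect_true(all(ro@wx >= 0))
    expect_true(all(ro@wy >= 0))
  }
  assign("popFit", list(fit = fit, stim = stim, rs = rs, gt = gt),
         envir = .fixtureCache)
})

test_that("a constant-response neuron is flagged as undefined FEVE", {
  tw <- tinyWorld()
  pres <- miniV1:::presentationTable(tw$stim)
  resp <- matrix(2, nrow(pres), 1)
  rs <- new("ResponseSet", responses = resp, presentation = pres,
            category = integer(0))
  testI <- which(splitLabels(tw$stim) == "test")
  expect_warning(
    out <- feve(miniV1:::repeatMatrix(rs, 1, testI), rep(2, length(testI))),
    "undefined")
  expect_true(is.na(out))
})

test_that("minimodel fitting learns a tiny planted neuron", {
  tw <- tinyWorld()
  rs <- simulateResponses(tw$neurons, tw$stim, seed = 44, noise = "none",
                          conv1Feats = tw$feats)
  fit <- fitMinimodel(tw$stim, rs, neuron = 1, conv1 = tw$conv1,
                      config = trainConfig(scheduleScale = 0.3,
                                           batchSize = 8L, wcDecay = 0.2,
                                           seed = 45,
                                           checkInvariants = TRUE),
                      nOutputChannels = 8L, conv1Feats = tw$feats)
  # validation-selected snapshot is never worse than the initialization
  expect_gte(fit@log$bestValScore, fit@log$epochs$valScore[1] - 1e-9)
  expect_gt(fit@log$bestValScore, 0.2)
  expect_true(all(fit@readout@wx >= 0))
  # with lambda = 0 the Hoyer term contributes nothing: the fit is identical
  fit0 <- fitMinimodel(tw$stim, rs, neuron = 1, conv1 = tw$conv1,
                       config = trainConfig(scheduleScale = 0.3,
                                            batchSize = 8L, wcDecay = 0.2,
                                            seed = 45, lambda = 0),
                       nOutputChannels = 8L, conv1Feats = tw$feats)
  expect_equal(fit0@readout@wc, fit@readout@wc, tolerance = 1e-12)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  tw <- tinyWorld()
  rs <- simulateResponses(tw$neurons, tw$stim, seed = 46,
                          conv1Feats = tw$feats)
  badFeats <- tw$feats
  badFeats[1, 1, , 1] <- NaN
  expect_error(
    fitMinimodel(tw$stim, rs, neuron = 1, conv1 = tw$conv1,
                 config = trainConfig(scheduleScale = 0.02, batchSize = 16L),
                 nOutputChannels = 4L, conv1Feats = badFeats),
    "diverged")
})
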