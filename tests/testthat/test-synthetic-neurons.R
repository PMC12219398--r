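test_that("ground-truth neurons have the declared structure", {
  tw <- tinyWorld()
  expect_length(tw$neurons, 3L)
  for (nn in tw$neurons) {
    expect_identical(nActiveChannels(nn), 3L)
    expect_true(all(nn@readout@wx >= 0))
    expect_true(all(nn@readout@wy >= 0))
    expect_gt(nn@gain, 0)
  }
  # parameters depend only on (seed, index): a larger population reproduces
  # the same leading neurons
  more <- makeGroundTruthPopulation(tw$conv1, tw$stim, nNeurons = 4,
                                    channelsPerNeuron = 3, seed = 103,
                                    conv1Feats = tw$feats)
  expect_equal(more[[2L]]@conv2Spatial, tw$neurons[[2L]]@conv2Spatial)
  expect_equal(more[[2L]]@readout@wc, tw$neurons[[2L]]@readout@wc)
})

test_that("simulated responses follow the presentation bookkeeping", {
  tw <- tinyWorld()
  rs <- simulateResponses(tw$neurons, tw$stim, seed = 7,
                          conv1Feats = tw$feats)
  pres <- presentationMap(rs)
  split <- splitLabels(tw$stim)
  J <- testRepeats(tw$stim)
  expect_identical(nrow(pres),
                   sum(split != "test") + J * sum(split == "test"))
  counts <- table(pres$image)
  expect_true(all(counts[as.character(which(split == "test"))] == J))
  expect_true(all(counts[as.character(which(split != "test"))] == 1))
  expect_true(all(responses(rs) >= 0))
  # determinism
  rs2 <- simulateResponses(tw$neurons, tw$stim, seed = 7,
                           conv1Feats = tw$feats)
  expect_identical(responses(rs2), responses(rs))
})

test_that("a vanishing gain yields all-zero Poisson responses", {
  tw <- tinyWorld()
  nn <- tw$neurons[[1L]]
  nn@gain <- 1e-12
  rs <- simulateResponses(list(nn), tw$stim, seed = 8, conv1Feats = tw$feats)
  expect_true(all(responses(rs) == 0))
})

test_that("Poisson responses have matching mean and variance per image", {
  tw <- tinyWorld()
  nn <- tw$neurons[[1L]]
  rate <- nn@gain * minimodelPredict(nn, tw$feats)[1L]
  draws <- withSeed(9, rpois(10000, rate))
  se <- sqrt(rate / 10000)
  expect_lt(abs(mean(draws) - rate), 3 * se)
  # variance ~ mean within Monte-Carlo error
  expect_lt(abs(var(draws) - rate) / rate, 0.1)
})

test_that("noise calibration reaches the target mean FEV by monotone search", {
  withSeed(10, {
    rates <- matrix(runif(200 * 5, 0.5, 4), 200, 5)
    g <- calibrateNoiseToFEV(rates, 0.99)
    expect_lt(abs(attr(g, "achievedFEV") - 0.99), 0.001)
    expect_gt(as.numeric(g), 10)
    # fixed point: target equal to the gain-1 expected FEV returns gain ~ 1
    s2 <- apply(rates, 2, var); m <- colMeans(rates)
    current <- mean(s2 / (s2 + m))
    g1 <- calibrateNoiseToFEV(rates, current)
    expect_lt(abs(as.numeric(g1) - 1), 0.05)
    # monotone in the gain over a grid
    fevAt <- function(g) mean(g * s2 / (g * s2 + m))
    grid <- sapply(10^seq(-2, 2, length.out = 9), fevAt)
    expect_true(all(diff(grid) >= 0))
    # simulated FEV agrees with the calibrated expectation
    gg <- as.numeric(calibrateNoiseToFEV(rates, 0.5))
    sim <- sapply(1:5, function(j) {
      r <- matrix(rpois(200 * 10, gg * rates[, j]), 200, 10)
      fev(r)
    })
    expect_lt(abs(mean(sim) - 0.5), 0.05)
  })
})

test_that("unreachable calibration targets are flagged", {
  rates <- matrix(runif(50, 1, 2), 50, 1)
  expect_warning(g <- calibrateNoiseToFEV(rates, 0.999,
                                          gainBounds = c(1e-3, 1e-2)),
                 "unreachable")
  expect_true(attr(g, "flagged"))
})
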