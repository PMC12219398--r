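test_that("fev matches an explicit-sum oracle on small repeat tables", {
  set.seed(1)
  for (trial in 1:5) {
    r <- matrix(rpois(15, 4) + runif(15), 5, 3)
    expect_equal(fev(r), fevOracle(r), tolerance = 1e-10)
  }
})

test_that("fev is 1 for identical repeats and ~0 for pure noise", {
  r <- matrix(rep(c(1, 3, 7, 2, 5), 4), 5, 4)
  expect_equal(fev(r), 1)
  noise <- withSeed(7, matrix(rnorm(200 * 10), 200, 10))
  expect_lt(abs(fev(noise)), 0.05)
})

test_that("fev recovers a planted signal/noise ratio", {
  r <- plantedRepeats(I = 500, J = 10, s2 = 2, v = 3, seed = 5)
  expect_lt(abs(fev(r) - 2 / 5), 0.03)
})

test_that("fev flags degenerate inputs", {
  expect_warning(out <- fev(matrix(1, 5, 3)), "undefined")
  expect_true(is.na(out))
  expect_error(fev(matrix(1:5, 5, 1)), "repeats")
})

test_that("fev handles ragged repeats, excluding single-repeat images", {
  r <- list(c(1, 2, 3), c(4, 6), 5, c(2, 2, 4))
  vals <- unlist(r)
  noise <- mean(c(var(c(1, 2, 3)), var(c(4, 6)), var(c(2, 2, 4))))
  expect_equal(fev(r), (var(vals) - noise) / var(vals), tolerance = 1e-12)
})

test_that("feve is 1 for perfect predictions on noiseless data", {
  means <- c(1, 4, 2, 6, 3)
  r <- matrix(rep(means, 3), 5, 3)
  expect_equal(feve(r, means), 1)
})

test_that("feve is ~0 for the grand-mean prediction and ~1 for the truth", {
  r <- plantedRepeats(I = 500, J = 10, s2 = 4, v = 2, seed = 9)
  expect_lt(abs(feve(r, rep(mean(r), 500))), 0.05)
  withSeed(11, {
    rates <- runif(500, 2, 8)
    rp <- matrix(rpois(500 * 10, rates), 500, 10)
    expect_lt(abs(feve(rp, rates) - 1), 0.03)
  })
})

test_that("feve is invariant to a joint constant shift", {
  r <- plantedRepeats(I = 50, J = 4, s2 = 1, v = 1, seed = 13)
  o <- rowMeans(r)
  expect_equal(feve(r, o), feve(r + 10, o + 10), tolerance = 1e-10)
})

test_that("feve flags non-positive explainable variance", {
  # equal per-image means but across-repeat variance exceeding total variance
  r <- rbind(c(0, 10), c(10, 0), c(0, 10), c(10, 0))
  expect_warning(out <- feve(r, rep(5, 4)), "undefined")
  expect_true(is.na(out))
})

test_that("neuron selection uses a strict FEV threshold", {
  expect_identical(selectNeurons(c(0.15, 0.16, 0.14, NA)),
                   c(FALSE, TRUE, FALSE, FALSE))
})

test_that("fecvPairwise matches the explicit-sum oracle to 1e-10", {
  set.seed(21)
  for (trial in 1:5) {
    a <- rnorm(7, 0, 1)
    b <- rnorm(6, 1, 2)
    got <- fecvPairwise(c(a, b), rep(1:2, c(7, 6)))
    expect_equal(as.numeric(got), fecvPairOracle(a, b), tolerance = 1e-10)
  }
})

test_that("fecvPairwise averages over category pairs", {
  set.seed(22)
  vals <- c(rnorm(10, 0), rnorm(10, 2), rnorm(10, 5))
  cat_ <- rep(1:3, each = 10)
  got <- fecvPairwise(vals, cat_)
  pairs <- attr(got, "pairs")
  expect_length(pairs, 3L)
  manual <- mean(c(fecvPairOracle(vals[1:10], vals[11:20]),
                   fecvPairOracle(vals[1:10], vals[21:30]),
                   fecvPairOracle(vals[11:20], vals[21:30])))
  expect_equal(as.numeric(got), manual, tolerance = 1e-10)
})

test_that("fecvPairwise: constant distinct categories give 1; shuffles ~0", {
  vals <- rep(c(1, 3), each = 20)
  expect_equal(as.numeric(fecvPairwise(vals, rep(1:2, each = 20))), 1)
  # permutation null
  x <- plantedRepeats(I = 300, J = 1, s2 = 0, v = 1, seed = 23)[, 1]
  cat_ <- rep(1:2, each = 150)
  sh <- withSeed(24, replicate(100, {
    as.numeric(fecvPairwise(x, sample(cat_)))
  }))
  expect_lt(abs(mean(sh)), 0.02)
})

test_that("fecvPairwise recovers a planted between/within ratio of 0.5", {
  withSeed(25, {
    vals <- c(rnorm(300, 0, 1), rnorm(300, 2, 1))  # sigma2_cat = 1, total = 2
    got <- fecvPairwise(vals, rep(1:2, each = 300))
    expect_lt(abs(as.numeric(got) - 0.5), 0.05)
  })
})

test_that("negative finite-sample FECV estimates are retained", {
  withSeed(26, {
    reps <- replicate(200, as.numeric(
      fecvPairwise(rnorm(16), rep(1:2, each = 8))))
    expect_true(any(reps < 0))
  })
})

test_that("pooling diameter recovers the closed-form smoothed FWHM", {
  for (s in c(4, 8)) {
    n <- 24 * s
    w <- exp(-0.5 * ((seq_len(n) - n / 2) / s)^2)
    ro <- FactorizedReadout(w, w, 1)
    expected <- 2.3548 * sqrt(s^2 + 9)
    expect_lt(abs(poolingDiameter(ro, 1) - expected) / expected, 0.1)
  }
})

test_that("pooling diameter: isotropy and linearity in deg/sample", {
  w <- exp(-0.5 * ((1:64 - 30) / 5)^2)
  ro <- FactorizedReadout(w, w, 1)
  d1 <- poolingDiameter(ro, 1)
  expect_equal(d1, poolingDiameter(ro, 2) / 2, tolerance = 1e-12)
  # all-zero pooling vectors are flagged
  expect_warning(dz <- poolingDiameter(FactorizedReadout(rep(0, 8),
                                                         rep(0, 8), 1), 1),
                 "undefined")
  expect_true(is.na(dz))
})

test_that("input diversity: duplicated channels correlate perfectly and the
           measure is scale invariant", {
  tw <- tinyWorld()
  nn <- tw$neurons[[1L]]
  # duplicate one conv2 channel so two positive channels match exactly
  m <- ncol(nn@conv2Mix)
  nn2 <- nn
  nn2@conv2Mix <- cbind(nn@conv2Mix[, 1L], nn@conv2Mix[, 1L])
  nn2@bnGamma <- rep(nn@bnGamma[1L], 2)
  nn2@bnBeta <- rep(nn@bnBeta[1L], 2)
  nn2@bnMean <- rep(nn@bnMean[1L], 2)
  nn2@bnVar <- rep(nn@bnVar[1L], 2)
  nn2@readout@wc <- c(1, 0.5)
  expect_equal(inputDiversity(nn2, tw$feats), 1, tolerance = 1e-10)
  # positive rescaling of a channel's activations (gamma and beta jointly)
  # leaves the Pearson correlation unchanged
  nn3 <- nn2
  nn3@bnGamma <- nn2@bnGamma * c(3, 1)
  nn3@bnBeta <- nn2@bnBeta * c(3, 1)
  expect_equal(inputDiversity(nn3, tw$feats), 1, tolerance = 1e-8)
  # fewer than two positive channels is undefined
  nn4 <- nn2
  nn4@readout@wc <- c(1, -1)
  expect_warning(out <- inputDiversity(nn4, tw$feats), "undefined")
  expect_true(is.na(out))
})
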