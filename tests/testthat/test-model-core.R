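# brute-force "same"-padded cross-correlation oracle
crossCorrOracle <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(k); kw <- ncol(k)
  cy <- (kh - 1) / 2; cx <- (kw - 1) / 2
  out <- matrix(0, H, W)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    acc <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      y <- h + i - 1 - cy; x <- w + j - 1 - cx
      if (y >= 1 && y <= H && x >= 1 && x <= W) acc <- acc + k[i, j] * img[y, x]
    }
    out[h, w] <- acc
  }
  out
}

test_that("conv1 forward equals direct cross-correlation on a toy image", {
  withSeed(31, {
    img <- matrix(rnorm(64), 8, 8)
    k <- matrix(rnorm(9), 3, 3)
    got <- miniV1:::cc_conv1_forward(array(img, c(8, 8, 1)),
                                     array(k, c(3, 3, 1)))
    expect_equal(got[, , 1, 1], crossCorrOracle(img, k), tolerance = 1e-12)
    # delta kernel reproduces the image
    dk <- matrix(0, 3, 3); dk[2, 2] <- 1
    got2 <- miniV1:::cc_conv1_forward(array(img, c(8, 8, 1)),
                                      array(dk, c(3, 3, 1)))
    expect_equal(got2[, , 1, 1], img, tolerance = 1e-14)
  })
})

test_that("depthwise conv matches the oracle per channel", {
  withSeed(32, {
    x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    k <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    got <- miniV1:::cc_dwconv_forward(x, k)
    for (c in 1:3) for (n in 1:2)
      expect_equal(got[, , n, c], crossCorrOracle(x[, , n, c], k[, , c]),
                   tolerance = 1e-12)
  })
})

test_that("an all-zero image yields all-zero pre-pool activations under ELU", {
  cfg <- coreConfig(nLayers = 1L, channels = 4L, kernelSizes = 25L)
  core <- newConvCore(cfg, seed = 33)  # bn shift 0, stats (0, 1)
  out <- coreForward(core, array(0, c(32, 32, 1)))
  expect_true(all(out == 0))
})

test_that("core output shapes follow the same-padding convention for 1-4 layers", {
  withSeed(34, {
    imgs <- array(rnorm(36 * 44 * 2), c(36, 44, 2))
    for (L in 1:4) {
      cfg <- coreConfig(nLayers = L, channels = c(4L, 6L, 6L, 6L),
                        kernelSizes = c(25L, 5L, 3L, 3L))
      core <- newConvCore(cfg, seed = 30 + L)
      out <- coreForward(core, imgs)
      expect_identical(dim(out), c(18L, 22L, 2L, cfg$channels[L]))
    }
  })
})

test_that("factorized readout equals a dense rank-1 readout", {
  withSeed(35, {
    f <- array(rnorm(8 * 8 * 5 * 4), c(8, 8, 5, 4))
    ro <- FactorizedReadout(runif(8), runif(8), rnorm(4), offset = 0.3)
    z <- readoutForward(f, ro, rate = FALSE)
    dense <- sapply(1:5, function(n) {
      acc <- 0
      for (c in 1:4) for (y in 1:8) for (x in 1:8)
        acc <- acc + ro@wc[c] * ro@wy[y] * ro@wx[x] * f[y, x, n, c]
      acc + ro@offset
    })
    expect_equal(z, dense, tolerance = 1e-6)
  })
})

test_that("one-hot spatial readout selects a single position", {
  withSeed(36, {
    f <- array(rnorm(6 * 7 * 3 * 2), c(6, 7, 3, 2))
    wx <- rep(0, 7); wx[3] <- 1
    wy <- rep(0, 6); wy[5] <- 1
    wc <- rnorm(2)
    ro <- FactorizedReadout(wx, wy, wc)
    z <- readoutForward(f, ro, rate = FALSE)
    expect_equal(z, as.vector(f[5, 3, , 1] * wc[1] + f[5, 3, , 2] * wc[2]),
                 tolerance = 1e-12)
    # zero channel weights give a constant output
    z0 <- readoutForward(f, FactorizedReadout(wx, wy, c(0, 0), 0.2),
                         rate = FALSE)
    expect_equal(z0, rep(0.2, 3))
    # output rates are strictly positive
    expect_true(all(readoutForward(f, ro) > 0))
  })
})

test_that("projectNonnegative clamps wx/wy, leaves wc alone, idempotent", {
  ro <- FactorizedReadout(c(1, 2), c(3, 4), c(-1, 1))
  ro@wx <- c(-1, 2)  # bypass constructor validity to emulate a raw step
  p <- projectNonnegative(ro)
  expect_identical(p@wx, c(0, 2))
  expect_identical(p@wc, c(-1, 1))
  expect_identical(projectNonnegative(p), p)
})

test_that("spatialMap is the rank-1 outer product with separable sum", {
  ro <- FactorizedReadout(c(1, 0, 2), c(0, 1), c(1))
  m <- spatialMap(ro)
  expect_identical(m, outer(c(0, 1), c(1, 0, 2)))
  expect_identical(qr(m)$rank, 1L)
  expect_equal(sum(m), sum(ro@wx) * sum(ro@wy))
})

test_that("the LN-mode core is linear in the stimulus", {
  cfg <- coreConfig(nLayers = 2L, channels = c(4L, 6L),
                    kernelSizes = c(25L, 5L), activation = "identity",
                    poolType = "avg")
  core <- newConvCore(cfg, seed = 37)
  withSeed(38, {
    x <- array(rnorm(32 * 32), c(32, 32, 1))
    y <- array(rnorm(32 * 32), c(32, 32, 1))
    a <- 0.7; b <- -1.3
    mix <- array(a * x + b * y, c(32, 32, 1))
    fx <- coreForward(core, x)
    fy <- coreForward(core, y)
    fmix <- coreForward(core, mix)
    # linearity holds up to the constant batch-norm shift terms
    f0 <- coreForward(core, array(0, c(32, 32, 1)))
    lhs <- fmix - f0
    rhs <- a * (fx - f0) + b * (fy - f0)
    expect_equal(lhs, rhs, tolerance = 1e-5)
  })
})

test_that("max pooling backward routes gradients to the argmax", {
  withSeed(39, {
    x <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
    mp <- miniV1:::cc_maxpool2(x)
    gy <- array(1, dim(mp$y))
    gx <- miniV1:::cc_maxpool2_bwd(gy, mp$idx, 4L, 4L)
    expect_equal(sum(gx), length(mp$y))
    expect_true(all(gx[gx != 0] == 1))
    expect_equal(as.vector(x)[as.vector(mp$idx)], as.vector(mp$y),
                 tolerance = 1e-12)
  })
})
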