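test_that("natural images are zero-mean, standardized, and seed-deterministic", {
  s <- generateNaturalImages(4, 64, 128, spectralExponent = 1, seed = 0)
  imgs <- images(s)
  expect_identical(dim(imgs), c(64L, 128L, 4L))
  for (i in 1:4) {
    expect_lt(abs(mean(imgs[, , i])), 1e-6)
    expect_equal(sd(imgs[, , i]), 1, tolerance = 1e-8)
  }
  s2 <- generateNaturalImages(4, 64, 128, spectralExponent = 1, seed = 0)
  expect_identical(images(s2), imgs)
  expect_error(generateNaturalImages(2, 16, 64), ">= 32")
})

test_that("spectral exponent 0 gives a flat radial amplitude spectrum", {
  s <- generateNaturalImages(8, 64, 64, spectralExponent = 0, seed = 1)
  a <- 0
  for (i in 1:8) a <- a + Mod(fft(images(s)[, , i])) / 8
  f <- sqrt(outer(miniV1:::fftFreq(64)^2, miniV1:::fftFreq(64)^2, `+`))
  # radially averaged mean amplitude over mid-frequency annuli
  bins <- cut(f[f > 0.05 & f < 0.45], breaks = 8)
  rad <- tapply(a[f > 0.05 & f < 0.45], bins, mean)
  expect_lt((max(rad) - min(rad)) / mean(rad), 0.1)
})

test_that("a 1/f exponent produces decaying radial amplitudes", {
  s <- generateNaturalImages(1, 64, 64, spectralExponent = 1, seed = 2)
  a <- Mod(fft(images(s)[, , 1]))
  f <- sqrt(outer(miniV1:::fftFreq(64)^2, miniV1:::fftFreq(64)^2, `+`))
  lo <- mean(a[f > 0.02 & f < 0.08])
  hi <- mean(a[f > 0.3 & f < 0.45])
  expect_gt(lo / hi, 3)
})

test_that("texture sets have the declared counts, splits and determinism", {
  tx <- generateTextureSet(2, 20, 64, seed = 0)
  expect_identical(nImages(tx), 40L)
  expect_identical(as.vector(table(categoryIndex(tx))), c(20L, 20L))
  tab <- table(categoryIndex(tx), splitLabels(tx))
  expect_true(all(tab[, "train"] == tab[1, "train"]))
  expect_true(all(tab[, "test"] == tab[1, "test"]))
  tx2 <- generateTextureSet(2, 20, 64, seed = 0)
  expect_identical(images(tx2), images(tx))
  expect_error(generateTextureSet(2, 4, 64, parentSize = 64),
               "larger than parent")
})

test_that("within-category image correlation exceeds between-category", {
  # crops large relative to the parent, so exemplars share structure
  tx <- generateTextureSet(4, 21, 48, seed = 111, parentSize = 96,
                           testRepeats = 3)
  imgs <- images(tx)
  cat_ <- categoryIndex(tx)
  cm <- cor(matrix(imgs, ncol = dim(imgs)[3L]))
  same <- outer(cat_, cat_, `==`) & upper.tri(cm)
  diff <- outer(cat_, cat_, `!=`) & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))
})

test_that("the paper-scale texture call yields 16 x 350 exemplars", {
  # counting contract only; use small crops to keep it cheap
  tx <- generateTextureSet(16, 350, 32, seed = 3)
  expect_identical(nImages(tx), 5600L)
  expect_identical(length(unique(categoryIndex(tx))), 16L)
})

test_that("spectrum matching equalizes category-mean spectra", {
  tx <- tinyTextures()
  mx <- matchAmplitudeSpectra(tx, momentAdjust = FALSE)
  m <- images(mx)
  cat_ <- categoryIndex(mx)
  amp <- array(0, dim(m))
  for (i in seq_len(dim(m)[3L])) amp[, , i] <- Mod(fft(m[, , i]))
  grand <- apply(amp, c(1, 2), mean)
  for (k in unique(cat_)) {
    ak <- apply(amp[, , cat_ == k, drop = FALSE], c(1, 2), mean)
    expect_lt(sqrt(sum((ak - grand)^2)) / sqrt(sum(grand^2)), 1e-3)
  }
  expect_identical(categoryIndex(mx), categoryIndex(tx))
  expect_identical(nImages(mx), nImages(tx))
})

test_that("spectrum matching preserves Fourier phases", {
  tx <- tinyTextures()
  mx <- matchAmplitudeSpectra(tx, momentAdjust = FALSE)
  i <- 5L
  f0 <- fft(images(tx)[, , i] - mean(images(tx)[, , i]))
  f1 <- fft(images(mx)[, , i])
  big <- Mod(f0) > quantile(Mod(f0), 0.5)
  dphi <- Arg(f1[big] * Conj(f0[big]))
  expect_lt(max(abs(dphi)), 1e-6)
})

test_that("moment adjustment equalizes per-category pixel mean and sd", {
  tx <- tinyTextures()
  mx <- matchAmplitudeSpectra(tx)
  m <- images(mx)
  cat_ <- categoryIndex(mx)
  mom <- sapply(unique(cat_), function(k)
    c(mean(m[, , cat_ == k]), sd(as.vector(m[, , cat_ == k]))))
  expect_lt(diff(range(mom[1, ])), 1e-6)
  expect_lt(diff(range(mom[2, ])), 1e-6)
})

test_that("matching identical categories is a near no-op", {
  tx <- tinyTextures()
  imgs0 <- images(tx)[, , 1:6]
  same <- new("TextureStimulusSet",
              images = array(rep(imgs0, 2), c(dim(imgs0)[1:2], 12L)),
              split = rep(c(rep("train", 5), "test"), 2),
              category = rep(1:2, each = 6L), testRepeats = 2L,
              pixelToDegree = 1)
  mx <- matchAmplitudeSpectra(same, momentAdjust = FALSE)
  ref <- images(same)
  for (i in seq_len(12)) ref[, , i] <- ref[, , i] - mean(ref[, , i])
  expect_equal(images(mx), ref, tolerance = 1e-10)
})
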