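#' Construct a StimulusSet from an image array
#'
#' @param images numeric array `(H, W, N)`.
#' @param split character per-image labels in `train`/`val`/`test`.
#' @param testRepeats integer repeat count for test images.
#' @param pixelToDegree degrees of visual angle per pixel.
#' @return a [StimulusSet-class].
#' @export
StimulusSet <- function(images, split = rep("train", dim(images)[3L]),
                        testRepeats = 2L, pixelToDegree = 1) {
  new("StimulusSet", images = images, split = split,
      testRepeats = as.integer(testRepeats), pixelToDegree = pixelToDegree)
}

#' Generate naturalistic images with power-law amplitude spectra
#'
#' Draws Gaussian white noise per image and shapes its Fourier amplitudes to
#' `|A(f)| ~ f^(-spectralExponent)` (the 1/f statistics of natural scenes at
#' the default exponent 1). The DC bin is zeroed, so every image has exactly
#' zero mean; images are standardized to unit pixel variance. The last
#' `nTest` images are labeled `test` (presented `testRepeats` times during
#' simulation) and a fraction of the rest is labeled `val`.
#'
#' @param n number of images (>= 1).
#' @param height,width image size in pixels (>= 32).
#' @param spectralExponent exponent of the radial amplitude fall-off
#'   (0 = white noise).
#' @param seed integer seed; the generator is a pure function of it.
#' @param nTest number of test images.
#' @param valFraction fraction of the non-test images labeled `val`.
#' @param testRepeats repeats per test image.
#' @param pixelToDegree degrees of visual angle per pixel (default 1, the
#'   scale of the mouse stimulus display).
#' @return a [StimulusSet-class].
#' @examples
#' s <- generateNaturalImages(4, 64, 64, seed = 1)
#' dim(images(s))
#' @export
generateNaturalImages <- function(n, height, width, spectralExponent = 1,
                                  seed = 1L, nTest = 0L, valFraction = 0.1,
                                  testRepeats = 10L, pixelToDegree = 1) {
  stopIfNot(n >= 1, "n must be >= 1")
  stopIfNot(height >= 32 && width >= 32, "height and width must be >= 32")
  stopIfNot(nTest >= 0 && nTest < n, "nTest must be in [0, n)")
  fy <- fftFreq(height)
  fx <- fftFreq(width)
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- ifelse(f > 0, f^(-spectralExponent), 0)
  imgs <- withSeed(seed, {
    a <- array(0, c(height, width, n))
    for (i in seq_len(n)) {
      z <- stats::fft(matrix(rnorm(height * width), height, width))
      img <- Re(stats::fft(z * amp, inverse = TRUE)) / (height * width)
      s <- stats::sd(img)
      if (s > 0) img <- img / s
      a[, , i] <- img
    }
    a
  })
  nRest <- n - nTest
  nVal <- floor(valFraction * nRest)
  split <- c(rep("train", nRest - nVal), rep("val", nVal), rep("test", nTest))
  StimulusSet(imgs, split, testRepeats = max(2L, testRepeats),
              pixelToDegree = pixelToDegree)
}

# oriented log-bandpass parent texture with a category-specific pointwise
# nonlinearity; returns a (size x size) matrix, zero mean, unit sd
parentTexture <- function(size, theta, freq, exponent,
                          thetaBw = pi / 10, freqBwOct = 0.5) {
  f_y <- fftFreq(size)
  f <- sqrt(outer(f_y^2, f_y^2, `+`))
  ang <- atan2(outer(f_y, rep(1, size)), outer(rep(1, size), f_y))
  d <- (ang - theta + pi / 2) %% pi - pi / 2   # orientation difference, period pi
  filt <- exp(-d^2 / (2 * thetaBw^2)) *
    ifelse(f > 0, exp(-(log2(pmax(f, 1e-12) / freq))^2 / (2 * freqBwOct^2)), 0)
  z <- stats::fft(matrix(rnorm(size * size), size, size))
  x <- Re(stats::fft(z * filt, inverse = TRUE)) / (size * size)
  x <- x / stats::sd(x)
  x <- sign(x) * abs(x)^exponent   # category-specific higher-order statistics
  x <- x - mean(x)
  x / stats::sd(x)
}

# bilinear sample of matrix p at fractional coordinates (y, x)
bilinearSample <- function(p, y, x) {
  y0 <- pmin(pmax(floor(y), 1L), nrow(p) - 1L)
  x0 <- pmin(pmax(floor(x), 1L), ncol(p) - 1L)
  dy <- y - y0
  dx <- x - x0
  i00 <- cbind(y0, x0)
  p[i00] * (1 - dy) * (1 - dx) + p[cbind(y0 + 1L, x0)] * dy * (1 - dx) +
    p[cbind(y0, x0 + 1L)] * (1 - dy) * dx + p[cbind(y0 + 1L, x0 + 1L)] * dy * dx
}

#' Generate a synthetic texture-category stimulus set
#'
#' One large procedural "parent" texture is synthesized per category
#' (oriented band-pass noise passed through a category-specific pointwise
#' nonlinearity, so categories differ in orientation, spatial frequency and
#' higher-order statistics). Exemplars are crops of the parent at random
#' locations, small random rotations and random scales. Each category is
#' split into the same number of train and test exemplars.
#'
#' @param kCategories number of categories (>= 2).
#' @param exemplarsPerCategory exemplars drawn per category.
#' @param cropSize exemplar size in px: a scalar (square) or `c(height, width)`.
#' @param seed integer seed.
#' @param parentSize side of the square parent texture in px.
#' @param testFraction fraction of exemplars per category used as test
#'   exemplars (default 1/7, i.e., 50 of 350).
#' @param rotationRange maximal |rotation| of a crop in radians.
#' @param scaleRange range of the crop scale factor.
#' @param orientationBandwidth angular width (radians) of the parent
#'   textures' orientation band; small values give strongly oriented
#'   categories, larger values mildly anisotropic ones whose identity is
#'   carried mainly by spatial frequency and higher-order statistics.
#' @param testRepeats repeats per test exemplar.
#' @param pixelToDegree degrees of visual angle per pixel.
#' @return a [TextureStimulusSet-class].
#' @export
generateTextureSet <- function(kCategories, exemplarsPerCategory, cropSize,
                               seed = 1L, parentSize = 256L,
                               testFraction = 1 / 7,
                               rotationRange = pi / 9,
                               scaleRange = c(0.85, 1.2),
                               orientationBandwidth = pi / 4,
                               testRepeats = 10L, pixelToDegree = 1) {
  stopIfNot(kCategories >= 2, "need at least 2 categories")
  if (length(cropSize) == 1L) cropSize <- c(cropSize, cropSize)
  h <- cropSize[1L]
  w <- cropSize[2L]
  maxR <- max(scaleRange) * sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  if (2 * maxR + 2 > parentSize)
    stop("crop (after rotation/scale) larger than parent texture",
         call. = FALSE)
  freqs <- c(0.05, 0.08, 0.12, 0.18)       # cycles / px, category bands
  expos <- c(1, 2, 0.5, 3)                 # pointwise nonlinearity exponents
  nTest <- max(1L, round(testFraction * exemplarsPerCategory))
  nTotal <- kCategories * exemplarsPerCategory
  res <- withSeed(seed, {
    imgs <- array(0, c(h, w, nTotal))
    u <- (seq_len(w) - (w + 1) / 2)
    v <- (seq_len(h) - (h + 1) / 2)
    uu <- outer(rep(1, h), u)
    vv <- outer(v, rep(1, w))
    idx <- 0L
    for (k in seq_len(kCategories)) {
      theta <- (k - 1) * pi / kCategories
      fk <- freqs[(k - 1L) %% length(freqs) + 1L]
      pk <- expos[((k - 1L) %/% length(freqs)) %% length(expos) + 1L]
      parent <- parentTexture(parentSize, theta, fk, pk,
                              thetaBw = orientationBandwidth)
      for (e in seq_len(exemplarsPerCategory)) {
        idx <- idx + 1L
        phi <- runif(1, -rotationRange, rotationRange)
        sc <- runif(1, scaleRange[1L], scaleRange[2L])
        cy <- runif(1, 1 + maxR, parentSize - maxR)
        cx <- runif(1, 1 + maxR, parentSize - maxR)
        ys <- cy + sc * (uu * sin(phi) + vv * cos(phi))
        xs <- cx + sc * (uu * cos(phi) - vv * sin(phi))
        im <- matrix(bilinearSample(parent, as.vector(ys), as.vector(xs)), h, w)
        im <- im - mean(im)
        s <- stats::sd(im)
        if (s > 0) im <- im / s
        imgs[, , idx] <- im
      }
    }
    imgs
  })
  split <- rep(c(rep("train", exemplarsPerCategory - nTest),
                 rep("test", nTest)), kCategories)
  category <- rep(seq_len(kCategories), each = exemplarsPerCategory)
  new("TextureStimulusSet", images = res, split = split,
      category = as.integer(category),
      testRepeats = as.integer(max(2L, testRepeats)),
      pixelToDegree = pixelToDegree)
}

#' Equalize the mean amplitude spectrum across texture categories
#'
#' Removes low-level spectral cues that distinguish categories: each image's
#' Fourier amplitudes are rescaled so that every category's mean amplitude
#' spectrum equals the grand average over all images, with phases untouched.
#' Frequency bins whose category-mean amplitude is zero are left unchanged
#' (with per-image zero mean this concerns only the DC bin). Afterwards
#' (`momentAdjust = TRUE`, the default) every category's pooled pixel mean
#' and standard deviation are set to the common reference values 0 and 1.
#'
#' The two goals interact: the per-category standardization rescales each
#' category's spectra uniformly by the reciprocal of its pooled standard
#' deviation, so exactly matched mean spectra and exactly equal pooled
#' moments cannot both hold when categories differ in amplitude dispersion
#' (as they do when their higher-order statistics differ). With the default
#' moment adjustment the category-mean spectra agree up to that small
#' residual factor; with `momentAdjust = FALSE` they agree to numerical
#' precision while the pooled standard deviations keep a residual spread.
#'
#' @param textures a [TextureStimulusSet-class] with >= 2 categories.
#' @param iterations match/standardize passes.
#' @param momentAdjust equalize per-category pooled mean/sd after matching.
#' @return a [TextureStimulusSet-class] with matched spectra.
#' @export
matchAmplitudeSpectra <- function(textures, iterations = 2L,
                                  momentAdjust = TRUE) {
  stopifnot(is(textures, "TextureStimulusSet"))
  imgs <- textures@images
  d <- dim(imgs)
  n <- d[3L]
  cat_ <- textures@category
  cats <- sort(unique(cat_))
  stopIfNot(length(cats) >= 2, "need >= 2 categories")
  # exact zero mean per image so the DC bin never re-enters
  for (i in seq_len(n)) imgs[, , i] <- imgs[, , i] - mean(imgs[, , i])
  for (it in seq_len(iterations)) {
    ff <- vector("list", n)
    amp <- array(0, c(d[1L], d[2L], n))
    for (i in seq_len(n)) {
      ff[[i]] <- stats::fft(imgs[, , i])
      amp[, , i] <- Mod(ff[[i]])
    }
    grand <- apply(amp, c(1L, 2L), mean)
    for (k in cats) {
      sel <- which(cat_ == k)
      ak <- apply(amp[, , sel, drop = FALSE], c(1L, 2L), mean)
      scale <- ifelse(ak > 0, grand / ak, 1)
      for (i in sel) {
        imgs[, , i] <- Re(stats::fft(ff[[i]] * scale, inverse = TRUE)) /
          (d[1L] * d[2L])
        imgs[, , i] <- imgs[, , i] - mean(imgs[, , i])
      }
    }
    # common reference moments: pooled mean 0 (exact), pooled sd 1
    if (momentAdjust) {
      for (k in cats) {
        sel <- which(cat_ == k)
        sdk <- stats::sd(as.vector(imgs[, , sel]))
        if (sdk > 0) imgs[, , sel] <- imgs[, , sel] / sdk
      }
    }
  }
  out <- textures
  out@images <- imgs
  out
}
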