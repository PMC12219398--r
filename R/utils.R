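# internal numeric helpers

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
eluPrime <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

applyActivation <- function(x, activation) {
  switch(activation,
    elu = elu(x),
    relu = pmax(x, 0),
    identity = x,
    stop("unknown activation: ", activation))
}

activationPrime <- function(x, activation) {
  switch(activation,
    elu = eluPrime(x),
    relu = as.numeric(x > 0),
    identity = rep_len(1, length(x)),
    stop("unknown activation: ", activation))
}

# truncated, renormalized Gaussian kernel (sigma in samples)
gaussianKernel1d <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# 1-D Gaussian smoothing with reflection padding at the edges
smoothGaussian1d <- function(x, sigma, truncate = 4) {
  if (sigma <= 0) return(x)
  k <- gaussianKernel1d(sigma, truncate)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(pmax(r:1, 1L), n)], x, x[pmin(pmax(n:(n - r + 1L), 1L), n)])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1L):(r + n)]
}

# full width at the outermost half-max crossings, linearly interpolated;
# positions are in (fractional) sample units
fwhmWidth <- function(y) {
  m <- max(y)
  if (m <= 0) return(NA_real_)
  h <- m / 2
  n <- length(y)
  above <- which(y >= h)
  iL <- above[1L]
  iR <- above[length(above)]
  left <- if (iL == 1L) 1 else iL - (y[iL] - h) / (y[iL] - y[iL - 1L])
  right <- if (iR == n) n else iR + (y[iR] - h) / (y[iR] - y[iR + 1L])
  right - left
}

#' Block-mean downsampling of an image stack
#'
#' Averages non-overlapping `factor x factor` pixel blocks (the resolution
#' reduction used before Gabor-model fitting). Trailing rows/columns that do
#' not fill a block are dropped.
#'
#' @param imgs array `(H, W, N)` or a single `(H, W)` matrix.
#' @param factor integer downsampling factor.
#' @return downsampled array/matrix.
#' @export
downsampleImages <- function(imgs, factor = 2L) {
  ds1 <- function(x) {
    h <- nrow(x) %/% factor
    w <- ncol(x) %/% factor
    x <- x[seq_len(factor * h), seq_len(factor * w), drop = FALSE]
    out <- matrix(0, h, w)
    for (i in seq_len(factor))
      for (j in seq_len(factor))
        out <- out + x[seq(i, by = factor, length.out = h),
                       seq(j, by = factor, length.out = w)]
    out / factor^2
  }
  if (is.matrix(imgs)) return(ds1(imgs))
  d <- dim(imgs)
  out <- array(0, c(d[1L] %/% factor, d[2L] %/% factor, d[3L]))
  for (n in seq_len(d[3L])) out[, , n] <- ds1(imgs[, , n])
  out
}

# 2x block-mean downsampling of an (H, W) matrix (dims must be even)
blockMean2 <- function(x) {
  h <- nrow(x) %/% 2L
  w <- ncol(x) %/% 2L
  x <- x[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  0.25 * (x[c(TRUE, FALSE), c(TRUE, FALSE)] + x[c(FALSE, TRUE), c(TRUE, FALSE)] +
          x[c(TRUE, FALSE), c(FALSE, TRUE)] + x[c(FALSE, TRUE), c(FALSE, TRUE)])
}

# FFT frequencies in cycles per sample, matching the layout of stats::fft
fftFreq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

# 2-D amplitude spectrum of an (H, W) image
amplitudeSpectrum <- function(x) Mod(stats::fft(x))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
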