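#' Construct a factorized readout
#'
#' @param wx,wy non-negative pooling weights over horizontal / vertical
#'   feature-map positions.
#' @param wc signed channel weights.
#' @param offset scalar added to the readout before the output nonlinearity.
#' @return a [FactorizedReadout-class].
#' @export
FactorizedReadout <- function(wx, wy, wc, offset = 0) {
  new("FactorizedReadout", wx = as.numeric(wx), wy = as.numeric(wy),
      wc = as.numeric(wc), offset = as.numeric(offset))
}

#' Apply a factorized readout to a feature tensor
#'
#' Computes, per stimulus, `z = sum_c wc[c] * sum_{y,x} wy[y] wx[x] F[y,x,c]
#' + offset` and maps it to a strictly positive rate by `ELU(z) + 1`. This is
#' exactly a dense readout whose weight tensor is the rank-1 outer product
#' `W[c, y, x] = wc[c] wy[y] wx[x]`.
#'
#' @param features array `(H, W, N, C)` from [coreForward()].
#' @param readout a [FactorizedReadout-class] with `length(wy) == H`,
#'   `length(wx) == W`, `length(wc) == C`.
#' @param rate if `FALSE`, return the linear readout `z` before the output
#'   nonlinearity.
#' @return numeric vector of length `N` (one value per stimulus).
#' @export
readoutForward <- function(features, readout, rate = TRUE) {
  d <- dim(features)
  stopIfNot(length(d) == 4L, "features must be (H, W, N, C)")
  stopIfNot(length(readout@wy) == d[1L] && length(readout@wx) == d[2L] &&
            length(readout@wc) == d[4L],
            "readout dimensions must match the feature tensor")
  s <- as.vector(outer(readout@wy, readout@wx))      # (H*W), rows fastest
  pooled <- matrix(s %*% matrix(features, nrow = d[1L] * d[2L]),
                   nrow = d[3L], ncol = d[4L])       # N x C
  z <- as.vector(pooled %*% readout@wc) + readout@offset
  if (!rate) return(z)
  r <- elu(z) + 1
  if (any(r <= 0)) stop("internal error: non-positive rate", call. = FALSE)
  r
}

# per-channel spatially pooled activations (N x C), the quantity the
# invariance analyses operate on
pooledChannels <- function(features, readout) {
  d <- dim(features)
  s <- as.vector(outer(readout@wy, readout@wx))
  matrix(s %*% matrix(features, nrow = d[1L] * d[2L]), nrow = d[3L],
         ncol = d[4L])
}

#' Clamp the spatial readout weights to be non-negative
#'
#' Element-wise `max(w, 0)` on `wx` and `wy` (applied after every optimizer
#' step during fitting); `wc` is left untouched. Idempotent.
#'
#' @param readout a [FactorizedReadout-class].
#' @return the projected readout.
#' @export
projectNonnegative <- function(readout) {
  readout@wx <- pmax(readout@wx, 0)
  readout@wy <- pmax(readout@wy, 0)
  readout
}

#' Combined spatial map of a factorized readout
#'
#' The outer product `W_xy = wy wx^T`, a rank-1 non-negative map showing
#' where the neuron pools from.
#'
#' @param readout a [FactorizedReadout-class].
#' @return numeric matrix `(H, W)`.
#' @export
spatialMap <- function(readout) {
  outer(readout@wy, readout@wx)
}
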