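#' Fraction of explainable variance (FEV)
#'
#' The proportion of a neuron's response variance attributable to the
#' stimulus: `FEV = (Var[r] - sigma2_noise) / Var[r]`, where `Var[r]` is the
#' variance over all trials and the noise variance is the average across-
#' repeat variance of the same stimulus, `sigma2_noise = E_i[ Var_j[r_ij] ]`.
#' All variances use the unbiased (n-1) normalization. Images with a single
#' repeat contribute to `Var[r]` but are excluded from the noise-variance
#' average.
#'
#' @param r repeat-structured responses of one neuron: an `I x J` matrix
#'   (rows = images, columns = repeats) or a list of per-image repeat vectors
#'   (ragged repeats allowed).
#' @return FEV estimate; negative finite-sample values are not clipped.
#'   `NA` (with a warning) when the total variance is zero.
#' @export
fev <- function(r) {
  r <- asRepeatList(r)
  all <- unlist(r, use.names = FALSE)
  vt <- stats::var(all)
  if (!isTRUE(vt > 0)) {
    warning("zero total variance: FEV undefined")
    return(NA_real_)
  }
  nj <- lengths(r)
  stopIfNot(sum(nj >= 2L) >= 2L, "need >= 2 repeats on >= 2 images")
  vnoise <- mean(vapply(r[nj >= 2L], stats::var, 0))
  (vt - vnoise) / vt
}

asRepeatList <- function(r) {
  if (is.matrix(r)) return(lapply(seq_len(nrow(r)), function(i) r[i, ]))
  if (is.list(r)) return(lapply(r, as.numeric))
  stop("r must be an I x J matrix or a list of repeat vectors", call. = FALSE)
}

#' Fraction of explainable variance explained (FEVE)
#'
#' The proportion of the explainable (stimulus-driven) variance captured by
#' the model's per-image predictions:
#' `FEVE = 1 - (MSE - sigma2_noise) / (Var[r] - sigma2_noise)`, with the MSE
#' taken over all trials against the per-image prediction. Equals 1 when the
#' predictions match the true per-image means on noiseless data and ~0 for a
#' constant prediction at the grand mean.
#'
#' @param r repeat-structured responses (see [fev()]).
#' @param o numeric vector of per-image model predictions, `length(o)` equal
#'   to the number of images.
#' @return FEVE estimate, or `NA` with a warning when the explainable
#'   variance is not positive.
#' @export
feve <- function(r, o) {
  r <- asRepeatList(r)
  stopIfNot(length(o) == length(r), "need one prediction per image")
  all <- unlist(r, use.names = FALSE)
  vt <- stats::var(all)
  nj <- lengths(r)
  stopIfNot(sum(nj >= 2L) >= 2L, "need >= 2 repeats on >= 2 images")
  vnoise <- mean(vapply(r[nj >= 2L], stats::var, 0))
  ev <- vt - vnoise
  if (!isTRUE(ev > 0)) {
    warning("non-positive explainable variance: FEVE undefined")
    return(NA_real_)
  }
  se <- unlist(lapply(seq_along(r), function(i) (r[[i]] - o[i])^2),
               use.names = FALSE)
  mse <- mean(se)
  1 - (mse - vnoise) / ev
}

#' Select neurons by explainable variance
#'
#' Keeps neurons whose FEV strictly exceeds the threshold (default 0.15, the
#' conventional reliability cut for reporting model performance).
#'
#' @param fevs numeric vector of per-neuron FEV values.
#' @param threshold inclusion threshold (strict inequality).
#' @return logical mask; `NA` FEV values are excluded.
#' @export
selectNeurons <- function(fevs, threshold = 0.15) {
  !is.na(fevs) & fevs > threshold
}

#' Pairwise fraction of explainable category variance (FECV)
#'
#' For every unordered pair of categories, the total variance over the pair's
#' trials (unbiased, pooled) is decomposed into the residual variance left
#' after removing category means (the average of the two within-category
#' variances) and the category variance (their difference); the pair's FECV
#' is `sigma2_category / sigma2_total`. The returned value is the mean over
#' pairs. Images and repeats both count as trials of their category. Negative
#' finite-sample estimates are retained (the category variance is a
#' difference of estimators and can be negative); pairs with zero total
#' variance are skipped with a message.
#'
#' @param values numeric vector of responses, one entry per trial.
#' @param category category label per trial (>= 2 distinct values).
#' @return mean pairwise FECV, with attribute `"pairs"` holding the
#'   per-pair estimates.
#' @export
fecvPairwise <- function(values, category) {
  stopIfNot(length(values) == length(category),
            "values and category must be aligned")
  cats <- sort(unique(category))
  stopIfNot(length(cats) >= 2, "need >= 2 categories")
  prs <- utils::combn(seq_along(cats), 2L)
  out <- numeric(0)
  nm <- character(0)
  for (p in seq_len(ncol(prs))) {
    a <- cats[prs[1L, p]]
    b <- cats[prs[2L, p]]
    va <- values[category == a]
    vb <- values[category == b]
    tot <- stats::var(c(va, vb))
    if (!isTRUE(tot > 0)) {
      message(sprintf("FECV: pair (%s, %s) has zero total variance; skipped",
                      a, b))
      next
    }
    resid <- mean(c(stats::var(va), stats::var(vb)))
    out <- c(out, (tot - resid) / tot)
    nm <- c(nm, paste(a, b, sep = "-"))
  }
  if (!length(out)) {
    warning("all category pairs degenerate: FECV undefined")
    return(NA_real_)
  }
  structure(mean(out), pairs = stats::setNames(out, nm))
}

#' Pooling diameter of a factorized readout, in degrees
#'
#' Each pooling vector is smoothed with a Gaussian of standard deviation 3
#' samples (truncated at 4 sigma, renormalized, reflecting edges), its full
#' width at half maximum is measured by linear interpolation between the
#' outermost half-max crossings, widths are converted to degrees of visual
#' angle, and the geometric mean of the two widths is returned. `degPerSample`
#' must be the visual angle per readout sample: image `pixelToDegree` times
#' the 2x pooling stride of the core for readouts over pooled feature maps.
#'
#' @param readout a [FactorizedReadout-class] (wx, wy non-negative).
#' @param degPerSample degrees of visual angle per readout sample.
#' @param smoothSigma smoothing standard deviation in samples.
#' @return pooling diameter in degrees; `NA` with a warning for an all-zero
#'   readout.
#' @export
poolingDiameter <- function(readout, degPerSample, smoothSigma = 3) {
  if (max(readout@wx) <= 0 || max(readout@wy) <= 0) {
    warning("all-zero pooling vector: pooling diameter undefined")
    return(NA_real_)
  }
  wxs <- fwhmWidth(smoothGaussian1d(readout@wx, smoothSigma))
  wys <- fwhmWidth(smoothGaussian1d(readout@wy, smoothSigma))
  sqrt(wxs * wys) * degPerSample
}

#' Input diversity of a minimodel
#'
#' The mean pairwise Pearson correlation among the spatially pooled
#' activations (weighted by `wx`, `wy`) of the conv2 channels with positive
#' readout weight `wc`, evaluated on a stimulus set. Low values mean the
#' neuron combines diverse excitatory inputs.
#'
#' @param minimodel a fitted [Minimodel-class].
#' @param stimuli a [StimulusSet-class], image array, or precomputed conv1
#'   feature array `(H', W', N, C1)`.
#' @return mean pairwise correlation; `NA` with a warning when fewer than two
#'   channels have positive weight.
#' @export
inputDiversity <- function(minimodel, stimuli) {
  pooled <- minimodelPooled(minimodel, stimuli)
  pos <- which(minimodel@readout@wc > 0)
  if (length(pos) < 2L) {
    warning("fewer than 2 positive-weight channels: input diversity undefined")
    return(NA_real_)
  }
  p <- pooled[, pos, drop = FALSE]
  keep <- apply(p, 2L, stats::sd) > 0
  p <- p[, keep, drop = FALSE]
  if (ncol(p) < 2L) {
    warning("fewer than 2 non-degenerate positive channels")
    return(NA_real_)
  }
  cm <- stats::cor(p)
  mean(cm[upper.tri(cm)])
}
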