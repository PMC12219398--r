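#' StimulusSet: a set of grayscale images with a train/val/test split
#'
#' Images are stored channels-last as a 3-D array `(height, width, n_images)`
#' of real values, zero mean per image at roughly unit scale. Each image
#' carries a split label in `train`/`val`/`test`; test images are presented
#' `testRepeats` times during simulation. `pixelToDegree` converts image
#' pixels into degrees of visual angle (used by [poolingDiameter()]).
#'
#' @slot images numeric 3-D array `(H, W, N)`.
#' @slot split character vector of length `N` in `train`, `val`, `test`.
#' @slot testRepeats integer, number of repeats per test image (>= 2).
#' @slot pixelToDegree numeric scalar, degrees of visual angle per pixel.
#' @export
setClass("StimulusSet",
  representation(images = "array", split = "character",
                 testRepeats = "integer", pixelToDegree = "numeric"),
  prototype(testRepeats = 2L, pixelToDegree = 1))

setValidity("StimulusSet", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a 3-D (H, W, N) array")
  if (length(object@split) != d[3L])
    return("split must have one label per image")
  bad <- setdiff(unique(object@split), c("train", "val", "test"))
  if (length(bad)) return(paste("unknown split labels:", paste(bad, collapse = ", ")))
  if (object@testRepeats < 2L) return("testRepeats must be >= 2")
  if (object@pixelToDegree <= 0) return("pixelToDegree must be positive")
  if (!all(is.finite(object@images))) return("images must be finite")
  TRUE
})

#' TextureStimulusSet: exemplars drawn from texture categories
#'
#' Extends [StimulusSet-class] with a per-image category index. Exemplars are
#' split into `train` and `test` roles (the `val` label is unused); test
#' exemplars are presented `testRepeats` times during simulation.
#'
#' @slot category integer vector, 1-based category index per image.
#' @export
setClass("TextureStimulusSet", contains = "StimulusSet",
  representation(category = "integer"))

setValidity("TextureStimulusSet", function(object) {
  n <- dim(object@images)[3L]
  if (length(object@category) != n) return("category must have one entry per image")
  if (length(unique(object@category)) < 2L) return("need >= 2 categories")
  if (any(object@split == "val")) return("texture sets use only train/test roles")
  tab <- table(object@category, object@split)
  if (nrow(tab) && any(apply(tab, 2L, function(x) length(unique(x)) != 1L)))
    return("every category must have the same number of train and test exemplars")
  TRUE
})

#' ResponseSet: neuron responses aligned to stimulus presentations
#'
#' Rows are presentations, columns are neurons. The presentation map links
#' each row to an `(image, repeat)` pair of the generating [StimulusSet-class];
#' a category column is carried along for texture stimuli.
#'
#' @slot responses numeric matrix `(n_presentations, n_neurons)`, finite, >= 0.
#' @slot presentation data.frame with columns `image` (1-based image index)
#'   and `rep` (1-based repeat index), one row per presentation.
#' @slot category integer vector per presentation (length 0 when absent).
#' @export
setClass("ResponseSet",
  representation(responses = "matrix", presentation = "data.frame",
                 category = "integer"))

setValidity("ResponseSet", function(object) {
  r <- object@responses
  if (!is.numeric(r)) return("responses must be numeric")
  if (nrow(object@presentation) != nrow(r))
    return("presentation map must have one row per presentation")
  if (!all(c("image", "rep") %in% names(object@presentation)))
    return("presentation map needs columns 'image' and 'rep'")
  if (!all(is.finite(r))) return("responses must be finite")
  if (any(r < 0)) return("responses must be non-negative")
  if (length(object@category) && length(object@category) != nrow(r))
    return("category must have one entry per presentation")
  TRUE
})

#' ConvCore: parameters of the shared convolutional core
#'
#' A stack of 1 to 4 convolutional layers. Layer 1 is a dense single-channel
#' convolution (kernel 25 by default); later layers are depth-separable
#' (a channel-wise spatial kernel followed by a 1x1 channel mix). Every layer
#' carries batch-normalization parameters and running statistics; convolutions
#' have no bias term. A 2x2 pooling step (max, or average in LN mode) follows
#' layer 1.
#'
#' @slot config list with elements `nLayers`, `channels`, `kernelSizes`,
#'   `activation` ("elu", "relu" or "identity"), `poolType` ("max" or "avg").
#' @slot layers list, one element per layer: `kernels` (kh, kw, C) for layer 1
#'   or the depthwise kernels for later layers, `mix` (C_in x C_out matrix,
#'   `NULL` for layer 1), `gamma`, `beta`, `runMean`, `runVar`.
#' @export
setClass("ConvCore", representation(config = "list", layers = "list"))

setValidity("ConvCore", function(object) {
  cfg <- object@config
  need <- c("nLayers", "channels", "kernelSizes", "activation", "poolType")
  if (!all(need %in% names(cfg)))
    return(paste("config must contain:", paste(need, collapse = ", ")))
  if (cfg$nLayers < 1L || cfg$nLayers > 4L) return("nLayers must be in 1..4")
  if (any(cfg$kernelSizes[seq_len(cfg$nLayers)] %% 2L == 0L))
    return("kernel sizes must be odd")
  if (any(cfg$channels[seq_len(cfg$nLayers)] < 1L))
    return("channel counts must be positive")
  if (length(object@layers) != cfg$nLayers)
    return("layers must match config$nLayers")
  TRUE
})

#' FactorizedReadout: rank-1 spatial pooling plus signed channel weights
#'
#' The spatial readout is the outer product of two non-negative vectors
#' `wy` (vertical) and `wx` (horizontal) over feature-map positions; `wc`
#' mixes channels with signed weights. The readout scalar
#' `z = sum_c wc[c] * sum_{y,x} wy[y] wx[x] F[y,x,c] + offset` is mapped to a
#' strictly positive firing rate by `ELU(z) + 1`.
#'
#' @slot wx,wy non-negative numeric vectors over horizontal / vertical
#'   feature-map positions.
#' @slot wc signed numeric vector over channels.
#' @slot offset numeric scalar added to the readout before the output
#'   nonlinearity (kept inside `ELU(.)+1` so the rate stays positive).
#' @export
setClass("FactorizedReadout",
  representation(wx = "numeric", wy = "numeric", wc = "numeric",
                 offset = "numeric"),
  prototype(offset = 0))

setValidity("FactorizedReadout", function(object) {
  if (length(object@offset) != 1L) return("offset must be a scalar")
  if (any(object@wx < 0) || any(object@wy < 0))
    return("wx and wy must be non-negative")
  TRUE
})

#' PopulationModel: shared core plus one readout per neuron
#'
#' @slot core a [ConvCore-class].
#' @slot readouts list of [FactorizedReadout-class], one per neuron.
#' @slot log list of training diagnostics (per-epoch losses and validation
#'   scores; empty for untrained models).
#' @export
setClass("PopulationModel",
  representation(core = "ConvCore", readouts = "list", log = "list"),
  prototype(log = list()))

setValidity("PopulationModel", function(object) {
  if (!length(object@readouts)) return("need at least one readout")
  ok <- vapply(object@readouts, function(r) is(r, "FactorizedReadout"), TRUE)
  if (!all(ok)) return("readouts must be FactorizedReadout objects")
  TRUE
})

#' Minimodel: a per-neuron two-layer encoder with a frozen first layer
#'
#' conv1 is a frozen 1-layer [ConvCore-class] (16 kernels of size 25, ReLU,
#' 2x2 max pool) shared across neurons. conv2 is neuron-specific: a
#' channel-wise spatial kernel per conv1 channel, a 1x1 mix to `M` output
#' channels, batch normalization and a ReLU. The factorized readout then
#' pools space and mixes channels; the Hoyer-Square penalty used during
#' fitting drives entries of `wc` to zero, so the number of active channels
#' (`|wc| > 1e-6`) measures model size.
#'
#' @slot conv1 frozen [ConvCore-class] (1 layer).
#' @slot conv2Spatial numeric array `(k, k, C1)` of depthwise kernels.
#' @slot conv2Mix numeric matrix `(C1, M)`.
#' @slot bnGamma,bnBeta,bnMean,bnVar numeric vectors of length `M`.
#' @slot readout a [FactorizedReadout-class] over the conv2 output.
#' @slot lambda numeric, Hoyer-Square strength used during fitting.
#' @slot log list of training diagnostics.
#' @export
setClass("Minimodel",
  representation(conv1 = "ConvCore", conv2Spatial = "array",
                 conv2Mix = "matrix", bnGamma = "numeric", bnBeta = "numeric",
                 bnMean = "numeric", bnVar = "numeric",
                 readout = "FactorizedReadout", lambda = "numeric",
                 log = "list"),
  prototype(lambda = 0, log = list()))

setValidity("Minimodel", function(object) {
  m <- ncol(object@conv2Mix)
  if (dim(object@conv2Spatial)[3L] != nrow(object@conv2Mix))
    return("conv2Spatial channels must match conv2Mix rows")
  if (any(lengths(list(object@bnGamma, object@bnBeta, object@bnMean,
                       object@bnVar)) != m))
    return("batch-norm parameter lengths must equal ncol(conv2Mix)")
  if (any(object@bnVar < 0)) return("bnVar must be non-negative")
  TRUE
})

#' GroundTruthNeuron: a minimodel with a known response gain
#'
#' Synthetic ground truth for parameter-recovery tests: a fully specified
#' [Minimodel-class] whose output rate is scaled by a positive `gain` to an
#' expected event count per presentation, from which Poisson responses are
#' drawn.
#'
#' @slot gain positive scalar converting model output to expected counts.
#' @export
setClass("GroundTruthNeuron", contains = "Minimodel",
  representation(gain = "numeric"))

setValidity("GroundTruthNeuron", function(object) {
  if (length(object@gain) != 1L || object@gain <= 0)
    return("gain must be a positive scalar")
  if (nActiveChannels(object) < 1L) return("need at least one active channel")
  TRUE
})
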