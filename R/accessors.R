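#' @describeIn miniV1-generics image array of a StimulusSet, `(H, W, N)`.
#' @export
setMethod("images", "StimulusSet", function(x) x@images)

#' @describeIn miniV1-generics number of images.
#' @export
setMethod("nImages", "StimulusSet", function(x) dim(x@images)[3L])

#' @describeIn miniV1-generics split label per image.
#' @export
setMethod("splitLabels", "StimulusSet", function(x) x@split)

#' @describeIn miniV1-generics category index per image of a texture set.
#' @export
setMethod("categoryIndex", "TextureStimulusSet", function(x) x@category)

#' @describeIn miniV1-generics response matrix `(presentations, neurons)`.
#' @export
setMethod("responses", "ResponseSet", function(x) x@responses)

#' @describeIn miniV1-generics presentation-to-(image, repeat) map.
#' @export
setMethod("presentationMap", "ResponseSet", function(x) x@presentation)

#' @describeIn miniV1-generics category index per presentation (or NULL).
#' @export
setMethod("categoryIndex", "ResponseSet", function(x)
  if (length(x@category)) x@category else NULL)

#' @describeIn miniV1-generics number of neurons in a ResponseSet.
#' @export
setMethod("nNeurons", "ResponseSet", function(x) ncol(x@responses))

#' @describeIn miniV1-generics number of neurons in a PopulationModel.
#' @export
setMethod("nNeurons", "PopulationModel", function(x) length(x@readouts))

#' @describeIn miniV1-generics readout of neuron `i` of a PopulationModel.
#' @param i neuron index.
#' @export
setMethod("readout", "PopulationModel", function(x, i = 1L) x@readouts[[i]])

#' @describeIn miniV1-generics readout of a Minimodel.
#' @export
setMethod("readout", "Minimodel", function(x, ...) x@readout)

#' Number of repeats per test image
#' @param x a [StimulusSet-class].
#' @return integer repeat count J.
#' @export
testRepeats <- function(x) {
  stopifnot(is(x, "StimulusSet"))
  x@testRepeats
}

#' Degrees of visual angle per image pixel
#' @param x a [StimulusSet-class].
#' @export
pixelToDegree <- function(x) {
  stopifnot(is(x, "StimulusSet"))
  x@pixelToDegree
}

#' Count the active conv2 channels of a minimodel
#'
#' A channel is active when its readout weight exceeds the documented
#' tolerance `|wc| > 1e-6`; the Hoyer-Square penalty drives pruned weights to
#' (near-)exact zero, so the count is insensitive to the exact threshold.
#'
#' @param x a [Minimodel-class].
#' @param tol magnitude threshold for an active channel.
#' @return integer count.
#' @export
nActiveChannels <- function(x, tol = 1e-6) {
  stopifnot(is(x, "Minimodel"))
  sum(abs(x@readout@wc) > tol)
}

setMethod("show", "StimulusSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("%s: %d images of %d x %d px (%.3g deg/px)\n", class(object),
              d[3L], d[1L], d[2L], object@pixelToDegree))
  tab <- table(factor(object@split, c("train", "val", "test")))
  cat(sprintf("  split: %d train / %d val / %d test (J = %d repeats)\n",
              tab[["train"]], tab[["val"]], tab[["test"]], object@testRepeats))
  if (is(object, "TextureStimulusSet"))
    cat(sprintf("  categories: %d\n", length(unique(object@category))))
})

setMethod("show", "ResponseSet", function(object) {
  cat(sprintf("ResponseSet: %d presentations x %d neurons\n",
              nrow(object@responses), ncol(object@responses)))
  cat(sprintf("  mean response %.3f; %d distinct images\n",
              mean(object@responses), length(unique(object@presentation$image))))
})

setMethod("show", "ConvCore", function(object) {
  cfg <- object@config
  cat(sprintf("ConvCore: %d layer(s), channels %s, kernels %s, %s/%s-pool\n",
              cfg$nLayers,
              paste(cfg$channels[seq_len(cfg$nLayers)], collapse = "-"),
              paste(cfg$kernelSizes[seq_len(cfg$nLayers)], collapse = "/"),
              cfg$activation, cfg$poolType))
})

setMethod("show", "PopulationModel", function(object) {
  cat(sprintf("PopulationModel: %d neurons\n", length(object@readouts)))
  show(object@core)
  if (length(object@log$val))
    cat(sprintf("  best validation score %.3f (epoch %d)\n",
                max(object@log$val, na.rm = TRUE),
                which.max(object@log$val)))
})

setMethod("show", "Minimodel", function(object) {
  cat(sprintf("Minimodel: %d conv1 channels -> %d conv2 channels (%d active), lambda = %g\n",
              nrow(object@conv2Mix), ncol(object@conv2Mix),
              nActiveChannels(object), object@lambda))
})

setMethod("show", "GroundTruthNeuron", function(object) {
  callNextMethod()
  cat(sprintf("  gain = %.3g\n", object@gain))
})
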