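#' @name miniV1-generics
#' @title Generics for miniV1 containers
#' @description Accessor and simulation generics for the stimulus, response
#'   and model classes.
#' @param object,x an object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname miniV1-generics
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname miniV1-generics
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname miniV1-generics
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' @rdname miniV1-generics
#' @export
setGeneric("categoryIndex", function(x) standardGeneric("categoryIndex"))

#' @rdname miniV1-generics
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname miniV1-generics
#' @export
setGeneric("presentationMap", function(x) standardGeneric("presentationMap"))

#' @rdname miniV1-generics
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname miniV1-generics
#' @export
setGeneric("readout", function(x, ...) standardGeneric("readout"))

#' Simulate responses of model neurons to a stimulus set
#'
#' Runs the generating model forward on every image, scales the predicted
#' rate by the neuron gain, and draws one response per presentation
#' (training/validation images once, test images `testRepeats(stimuli)`
#' times, independently per repeat). With `noise = "poisson"` responses are
#' Poisson counts; with `"none"` the expected rates are returned, which is
#' the noiseless limit used by parameter-recovery tests.
#'
#' @param object a list of [GroundTruthNeuron-class] or a
#'   [PopulationModel-class].
#' @param stimuli a [StimulusSet-class].
#' @param seed integer seed for the Poisson draws.
#' @param ... method-specific arguments (`noise`, precomputed features).
#' @return a [ResponseSet-class].
#' @export
setGeneric("simulateResponses",
           function(object, stimuli, seed = 1L, ...)
             standardGeneric("simulateResponses"))
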