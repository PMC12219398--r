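# Single-file dataset and checkpoint containers.
#
# Containers are RDS files holding a flat named list of plain arrays with a
# fixed, validated schema (field names: images, split, test_repeat_count,
# pixel_to_degree, responses, image_index, repeat_index, category). RDS is
# the one self-describing array container available without extra
# dependencies; the schema is documented here and checked on read.

datasetSchema <- "miniV1-dataset-v1"
checkpointSchema <- "miniV1-checkpoint-v1"

#' Write a stimulus/response dataset container
#'
#' @param stimuli a [StimulusSet-class] (or [TextureStimulusSet-class]).
#' @param responseSet a [ResponseSet-class] aligned to `stimuli` (optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(stimuli, responseSet = NULL, path) {
  x <- list(schema = datasetSchema,
            images = images(stimuli),
            split = splitLabels(stimuli),
            test_repeat_count = testRepeats(stimuli),
            pixel_to_degree = pixelToDegree(stimuli))
  if (is(stimuli, "TextureStimulusSet"))
    x$image_category <- categoryIndex(stimuli)
  if (!is.null(responseSet)) {
    x$responses <- responses(responseSet)
    x$image_index <- presentationMap(responseSet)$image
    x$repeat_index <- presentationMap(responseSet)$rep
    cat_ <- categoryIndex(responseSet)
    if (!is.null(cat_)) x$category <- cat_
  }
  saveRDS(x, path)
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the schema and the presentation bookkeeping; missing fields are
#' reported by name (schema-error), inconsistent presentation maps as
#' integrity errors.
#'
#' @param path file written by [writeDataset()].
#' @return list with elements `stimuli` ([StimulusSet-class]) and
#'   `responses` ([ResponseSet-class] or `NULL`).
#' @export
readDataset <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  x <- readRDS(path)
  stopIfNot(identical(x$schema, datasetSchema),
            paste("not a", datasetSchema, "container"))
  for (f in c("images", "split", "test_repeat_count", "pixel_to_degree"))
    if (is.null(x[[f]]))
      stop(sprintf("schema-error: missing field '%s'", f), call. = FALSE)
  stimuli <- if (!is.null(x$image_category)) {
    new("TextureStimulusSet", images = x$images, split = x$split,
        category = as.integer(x$image_category),
        testRepeats = as.integer(x$test_repeat_count),
        pixelToDegree = x$pixel_to_degree)
  } else {
    StimulusSet(x$images, x$split, x$test_repeat_count, x$pixel_to_degree)
  }
  rs <- NULL
  if (!is.null(x$responses)) {
    for (f in c("image_index", "repeat_index"))
      if (is.null(x[[f]]))
        stop(sprintf("schema-error: missing field '%s'", f), call. = FALSE)
    n <- dim(x$images)[3L]
    if (any(x$image_index < 1L | x$image_index > n))
      stop("integrity-error: image_index out of range [1, n_images]",
           call. = FALSE)
    if (length(x$image_index) != nrow(x$responses))
      stop("integrity-error: presentation map length != response rows",
           call. = FALSE)
    rs <- new("ResponseSet", responses = x$responses,
              presentation = data.frame(image = as.integer(x$image_index),
                                        rep = as.integer(x$repeat_index)),
              category = as.integer(x$category %||% integer(0)))
  }
  list(stimuli = stimuli, responses = rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modelToList <- function(model) {
  if (is(model, "GroundTruthNeuron")) {
    x <- modelToList(as(model, "Minimodel"))
    x$type <- "GroundTruthNeuron"
    x$gain <- model@gain
    x
  } else if (is(model, "Minimodel")) {
    list(type = "Minimodel",
         conv1 = list(config = model@conv1@config,
                      layers = model@conv1@layers),
         conv2Spatial = model@conv2Spatial, conv2Mix = model@conv2Mix,
         bnGamma = model@bnGamma, bnBeta = model@bnBeta,
         bnMean = model@bnMean, bnVar = model@bnVar,
         readout = list(wx = model@readout@wx, wy = model@readout@wy,
                        wc = model@readout@wc, offset = model@readout@offset),
         lambda = model@lambda, log = model@log)
  } else if (is(model, "PopulationModel")) {
    list(type = "PopulationModel",
         core = list(config = model@core@config, layers = model@core@layers),
         readouts = lapply(model@readouts, function(r)
           list(wx = r@wx, wy = r@wy, wc = r@wc, offset = r@offset)),
         log = model@log)
  } else stop("unsupported model class: ", class(model))
}

modelFromList <- function(x) {
  ro <- function(r) FactorizedReadout(r$wx, r$wy, r$wc, r$offset)
  switch(x$type,
    GroundTruthNeuron = {
      mm <- modelFromList(c(x[setdiff(names(x), c("type", "gain"))],
                            list(type = "Minimodel")))
      new("GroundTruthNeuron", mm, gain = x$gain)
    },
    Minimodel = Minimodel(
      conv1 = new("ConvCore", config = x$conv1$config,
                  layers = x$conv1$layers),
      conv2Spatial = x$conv2Spatial, conv2Mix = x$conv2Mix,
      bnGamma = x$bnGamma, bnBeta = x$bnBeta, bnMean = x$bnMean,
      bnVar = x$bnVar, readout = ro(x$readout), lambda = x$lambda,
      log = x$log),
    PopulationModel = new("PopulationModel",
      core = new("ConvCore", config = x$core$config, layers = x$core$layers),
      readouts = lapply(x$readouts, ro), log = x$log),
    stop("unknown checkpoint type: ", x$type))
}

#' Save a model checkpoint
#'
#' Stores the configuration and all parameter arrays as plain lists;
#' `loadCheckpoint(saveCheckpoint(m, p))` reproduces forward passes
#' bit-identically. Lists of models (e.g., minimodels per neuron) are
#' supported.
#'
#' @param model a [PopulationModel-class], [Minimodel-class],
#'   [GroundTruthNeuron-class], or a list of such models.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  payload <- if (is.list(model) && !is(model, "Minimodel"))
    list(schema = checkpointSchema, multiple = TRUE,
         models = lapply(model, modelToList))
  else list(schema = checkpointSchema, multiple = FALSE,
            models = list(modelToList(model)))
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return the model, or a list of models for multi-model checkpoints.
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  stopIfNot(identical(x$schema, checkpointSchema),
            paste("not a", checkpointSchema, "container"))
  models <- lapply(x$models, modelFromList)
  if (isTRUE(x$multiple)) models else models[[1L]]
}
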