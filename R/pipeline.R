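#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end pipeline: 64 x 128 px stimuli at
#' 1 deg/px (the working geometry of the synthetic module), ground-truth
#' neurons with 4 active channels, and a reduced training schedule.
#'
#' @param ... overrides of the default fields.
#' @return a named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L, out = "miniV1-run",
    nImages = 600L, height = 64L, width = 128L, nTest = 60L,
    nNeurons = 4L, channelsPerNeuron = 4L, poolingSigmaPx = c(3, 9),
    noise = "poisson",
    scheduleScale = 0.05, batchSize = 64L, lambda = 0,
    nOutputChannels = 16L,
    textures = NULL,   # or list(kCategories =, exemplarsPerCategory =, cropSize =)
    verbose = TRUE)
  utils::modifyList(cfg, list(...))
}

pipelineLog <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

#' Run the simulate -> fit -> evaluate pipeline
#'
#' Executes, under one output directory: stimulus simulation (natural images,
#' ground-truth neurons, Poisson responses, written as a dataset container),
#' minimodel fitting for every neuron, the per-neuron metric report, and --
#' when a texture configuration is present -- the texture-invariance
#' analysis (spectrum matching, decoding, FECV comparison). A manifest
#' records the package version, seed, and MD5 hashes of the artifacts. A
#' failing stage halts the run with the stage name; artifacts of completed
#' stages persist.
#'
#' @param config a list from [pipelineConfig()].
#' @return list with the artifact paths, the metric report, and the manifest,
#'   invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- utils::modifyList(pipelineConfig(), config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "miniV1",
                   version = as.character(utils::packageVersion("miniV1")),
                   seed = cfg$seed, stages = list())
  paths <- list(dataset = file.path(cfg$out, "dataset.rds"),
                models = file.path(cfg$out, "minimodels.rds"),
                report = file.path(cfg$out, "report.csv"),
                manifest = file.path(cfg$out, "manifest.json"))
  finishStage <- function(name, files = character(0)) {
    manifest$stages[[name]] <<- list(
      status = "ok",
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- simulate ----
  sim <- runStage("simulate", {
    pipelineLog(cfg, "simulate: %d images, %d neurons", cfg$nImages,
                cfg$nNeurons)
    stim <- generateNaturalImages(cfg$nImages, cfg$height, cfg$width,
                                  seed = cfg$seed, nTest = cfg$nTest)
    conv1 <- makeConv1Bank(stim, seed = cfg$seed)
    neurons <- makeGroundTruthPopulation(conv1, stim, cfg$nNeurons,
                                         cfg$channelsPerNeuron,
                                         cfg$poolingSigmaPx,
                                         seed = cfg$seed)
    rs <- simulateResponses(neurons, stim, seed = cfg$seed,
                            noise = cfg$noise)
    writeDataset(stim, rs, paths$dataset)
    list(stim = stim, conv1 = conv1, neurons = neurons, rs = rs)
  })
  finishStage("simulate", paths$dataset)

  # ---- fit-minimodels ----
  fits <- runStage("fit-minimodels", {
    feats <- conv1Features(sim$conv1, sim$stim)
    tc <- trainConfig(scheduleScale = cfg$scheduleScale,
                      batchSize = cfg$batchSize, wcDecay = 0.2,
                      lambda = cfg$lambda, seed = cfg$seed)
    lapply(seq_len(cfg$nNeurons), function(i) {
      pipelineLog(cfg, "fit-minimodels: neuron %d/%d", i, cfg$nNeurons)
      fitMinimodel(sim$stim, sim$rs, neuron = i, conv1 = sim$conv1,
                   config = tc, nOutputChannels = cfg$nOutputChannels,
                   conv1Feats = feats)
    })
  })
  saveCheckpoint(fits, paths$models)
  finishStage("fit-minimodels", paths$models)

  # ---- evaluate ----
  report <- runStage("evaluate", {
    evaluateNeurons(fits, sim$stim, sim$rs)
  })
  utils::write.csv(report, paths$report, row.names = FALSE)
  finishStage("evaluate", paths$report)

  # ---- analyze-invariance (optional) ----
  invariance <- NULL
  if (!is.null(cfg$textures)) {
    invariance <- runStage("analyze-invariance", {
      tx <- do.call(generateTextureSet,
                    c(cfg$textures, list(seed = cfg$seed + 1L)))
      tx <- matchAmplitudeSpectra(tx)
      rsT <- simulateResponses(sim$neurons, tx, seed = cfg$seed + 2L)
      cmp <- compareModelNeuronFECV(fits, rsT, tx, seed = cfg$seed + 3L)
      acc <- decodeCategories(rsT, tx)
      paths$invariance <<- file.path(cfg$out, "invariance.csv")
      utils::write.csv(cmp, paths$invariance, row.names = FALSE)
      list(comparison = cmp, decodingAccuracy = as.numeric(acc),
           correlation = attr(cmp, "correlation"))
    })
    finishStage("analyze-invariance", paths$invariance)
  }
  manifest$stages[["done"]] <- list(status = "ok")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, report = report, invariance = invariance,
                 manifest = manifest, models = fits, stimuli = sim$stim,
                 responses = sim$rs, neurons = sim$neurons))
}
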