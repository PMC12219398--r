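#' Per-neuron metric report
#'
#' Computes, for every neuron, the repeat-based FEV on the test images, the
#' model FEVE, the pooling diameter in degrees, the active-channel count,
#' the input diversity, and (when category annotations are present) the
#' pairwise FECV of the responses. FEV is reported raw and clipped to [0, 1]
#' (`fevClipped`); FEVE/FECV are left unclipped. The report is the tabular
#' output of the `evaluate` pipeline stage.
#'
#' @param models list of fitted [Minimodel-class] objects (one per neuron)
#'   or a [PopulationModel-class].
#' @param stimuli the [StimulusSet-class] the responses were recorded to.
#' @param responseSet the [ResponseSet-class].
#' @param conv1Feats optional precomputed conv1 features (minimodels only).
#' @return data.frame with one row per neuron.
#' @export
evaluateNeurons <- function(models, stimuli, responseSet, conv1Feats = NULL) {
  testImgs <- which(splitLabels(stimuli) == "test")
  stopIfNot(length(testImgs) >= 2L, "need >= 2 test images")
  degPerSample <- pixelToDegree(stimuli) * 2  # readouts live on pooled maps
  isPop <- is(models, "PopulationModel")
  if (isPop) {
    nn <- nNeurons(models)
    preds <- populationPredict(models, stimuli)
    readouts <- models@readouts
  } else {
    nn <- length(models)
    if (is.null(conv1Feats))
      conv1Feats <- conv1Features(models[[1L]]@conv1, stimuli)
    preds <- vapply(models, function(m) minimodelPredict(m, conv1Feats),
                    numeric(nImages(stimuli)))
    readouts <- lapply(models, function(m) m@readout)
  }
  catTrial <- categoryIndex(responseSet)
  rows <- lapply(seq_len(nn), function(i) {
    rep_ <- repeatMatrix(responseSet, i, testImgs)
    fv <- suppressWarnings(fev(rep_))
    fe <- suppressWarnings(feve(rep_, preds[testImgs, i]))
    data.frame(
      neuron = i,
      fev = fv,
      fevClipped = pmin(pmax(fv, 0), 1),
      feve = fe,
      poolingDiameterDeg = suppressWarnings(
        poolingDiameter(readouts[[i]], degPerSample)),
      nActiveChannels = if (isPop) NA_integer_ else nActiveChannels(models[[i]]),
      inputDiversity = if (isPop) NA_real_ else suppressWarnings(
        inputDiversity(models[[i]], conv1Feats)),
      fecv = if (is.null(catTrial)) NA_real_ else suppressMessages(
        as.numeric(fecvPairwise(responses(responseSet)[, i], catTrial))))
  })
  do.call(rbind, rows)
}
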