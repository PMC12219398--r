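Package: miniV1
Title: Simplified Encoding Minimodels of Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer convolutional encoding models of visual cortical
    neurons with factorized rank-1 readouts, per-neuron sparse "minimodels"
    regularized by the Hoyer-Square penalty, the FEV/FEVE/FECV metric family
    for repeat-structured responses, Gabor and linear-nonlinear baselines,
    and a texture-invariance analysis pipeline. Includes a synthetic-data
    module that generates naturalistic (1/f) images, spectrum-matched
    texture categories, and ground-truth model neurons with Poisson
    observation noise, so that fitting and metrics are testable end to end
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    nnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
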