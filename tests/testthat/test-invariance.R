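test_that("decoding is at chance for shuffled labels and high for separable
           responses", {
  xw <- textureWorld()
  K <- length(unique(categoryIndex(xw$tx)))
  # separable synthetic responses: distinct category means, small noise
  pres <- presentationMap(xw$rs)
  catTrial <- categoryIndex(xw$rs)
  nN <- 12L
  mu <- withSeed(123, matrix(runif(K * nN, 0, 4), K, nN))
  resp <- mu[catTrial, ] +
    withSeed(124, matrix(rnorm(length(catTrial) * nN, 0, 0.2), ncol = nN))
  sep <- new("ResponseSet", responses = pmax(resp, 0), presentation = pres,
             category = catTrial)
  expect_gt(decodeCategories(sep, xw$tx), 0.95)
  # chance level on shuffled labels, within 3 binomial standard errors
  accS <- decodeCategories(sep, xw$tx, shuffleLabels = TRUE, seed = 125)
  nTest <- attr(accS, "nTest")
  expect_lt(abs(accS - 1 / K), 3 * sqrt((1 / K) * (1 - 1 / K) / nTest))
  # invariance to per-neuron affine rescaling
  aff <- sweep(sweep(pmax(resp, 0), 2, seq(0.5, 3, length.out = nN), `*`),
               2, seq(0, 2, length.out = nN), `+`)
  sepA <- new("ResponseSet", responses = aff, presentation = pres,
              category = catTrial)
  expect_equal(as.numeric(decodeCategories(sepA, xw$tx)),
               as.numeric(decodeCategories(sep, xw$tx)))
})

test_that("decoding requires at least two categories", {
  xw <- textureWorld()
  one <- xw$tx
  one@category <- rep(1L, nImages(one))
  expect_error(decodeCategories(xw$rs, one), "categories")
})

test_that("stage-wise FECV has six ordered stages; the readout stage equals
           the FECV of the noiseless output", {
  xw <- textureWorld()
  nn <- xw$tw$neurons[[1L]]
  st <- stagewiseFECV(nn, xw$tx)
  expect_named(st, c("conv1", "pool", "conv2_spatial", "conv2_mix_relu",
                     "pooled_wxy", "readout"))
  rate <- minimodelPredict(nn, xw$txFeats)
  cat_ <- categoryIndex(xw$tx)
  expect_equal(unname(st["readout"]),
               as.numeric(fecvPairwise(rate, cat_)), tolerance = 1e-10)
  # shared precomputation gives identical results
  shared <- precomputeConv1Stages(xw$tw$conv1, xw$tx)
  expect_equal(stagewiseFECV(nn, xw$tx, shared), st, tolerance = 1e-12)
})

test_that("a wide spatial readout is more category invariant than a one-hot
           readout on the same conv weights", {
  xw <- textureWorld()
  nn <- xw$tw$neurons[[2L]]
  H <- length(nn@readout@wy); W <- length(nn@readout@wx)
  wide <- nn
  wide@readout@wy <- miniV1:::discretizedGaussian(H, H / 2, H / 3)
  wide@readout@wx <- miniV1:::discretizedGaussian(W, W / 2, W / 3)
  onehot <- nn
  onehot@readout@wy <- as.numeric(seq_len(H) == round(H / 2))
  onehot@readout@wx <- as.numeric(seq_len(W) == round(W / 2))
  shared <- precomputeConv1Stages(xw$tw$conv1, xw$tx)
  sWide <- stagewiseFECV(wide, xw$tx, shared)
  sHot <- stagewiseFECV(onehot, xw$tx, shared)
  expect_gt(sWide["readout"], sHot["readout"])
})

test_that("model-vs-neuron FECV comparison is self-consistent", {
  xw <- textureWorld()
  cmp <- compareModelNeuronFECV(xw$tw$neurons, xw$rs, xw$tx, seed = 126,
                                conv1Feats = xw$txFeats)
  expect_identical(nrow(cmp), 3L)
  expect_true(is.finite(attr(cmp, "correlation")))
  expect_gt(attr(cmp, "gain"), 0)
  # with near-zero noise the model-side FECV approaches the noiseless value
  rates <- sapply(xw$tw$neurons, function(nn)
    minimodelPredict(nn, xw$txFeats))
  cat_ <- categoryIndex(xw$tx)
  noiseless <- sapply(seq_len(3), function(i)
    as.numeric(fecvPairwise(rates[presentationMap(xw$rs)$image, i],
                            categoryIndex(xw$rs))))
  # the recorded side stays fixed no matter the seed
  cmp2 <- compareModelNeuronFECV(xw$tw$neurons, xw$rs, xw$tx, seed = 127,
                                 conv1Feats = xw$txFeats)
  expect_equal(cmp2$fecvNeuron, cmp$fecvNeuron)
  expect_true(all(abs(noiseless) <= 1))
})

test_that("masked top stimuli are ranked and masked by the readout ellipse", {
  xw <- textureWorld()
  nn <- xw$tw$neurons[[1L]]
  top <- maskedTopStimuli(nn, xw$tx, nTop = 6L)
  expect_length(top$indices, 6L)
  expect_true(all(diff(top$output) <= 0))
  # weights vanish outside the dilated ellipse, and the mask multiplies the
  # images pointwise
  expect_true(any(top$mask == 0) || all(top$mask > 0))
  i <- top$indices[1L]
  expect_equal(top$maskedImages[, , 1L],
               images(xw$tx)[, , i] * top$mask, tolerance = 1e-12)
  # per-channel ranking returns one index set per conv2 channel, ordered by wc
  ch <- maskedTopStimuli(nn, xw$tx, perChannel = TRUE, nTopChannel = 4L)
  expect_length(ch, ncol(nn@conv2Mix))
  expect_true(all(lengths(ch) == 4L))
  # a flat readout falls back to the full image with a warning
  flat <- nn
  flat@readout@wx <- rep(0, length(nn@readout@wx))
  expect_warning(tf <- maskedTopStimuli(flat, xw$tx, nTop = 3L), "flat")
  expect_true(all(tf$mask == 1))
})
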