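#' Construct a Minimodel from its parameter arrays
#'
#' @param conv1 frozen 1-layer [ConvCore-class].
#' @param conv2Spatial array `(k, k, C1)` of depthwise kernels.
#' @param conv2Mix matrix `(C1, M)`.
#' @param bnGamma,bnBeta,bnMean,bnVar batch-norm parameters of length `M`.
#' @param readout a [FactorizedReadout-class].
#' @param lambda Hoyer-Square strength used in fitting (bookkeeping).
#' @param log training log list.
#' @return a [Minimodel-class].
#' @export
Minimodel <- function(conv1, conv2Spatial, conv2Mix,
                      bnGamma = rep(1, ncol(conv2Mix)),
                      bnBeta = rep(0, ncol(conv2Mix)),
                      bnMean = rep(0, ncol(conv2Mix)),
                      bnVar = rep(1, ncol(conv2Mix)),
                      readout, lambda = 0, log = list()) {
  new("Minimodel", conv1 = conv1, conv2Spatial = conv2Spatial,
      conv2Mix = conv2Mix, bnGamma = bnGamma, bnBeta = bnBeta,
      bnMean = bnMean, bnVar = bnVar, readout = readout, lambda = lambda,
      log = log)
}

# features: StimulusSet / (H, W, N) images -> frozen conv1 features;
# a 4-D array is taken to be precomputed conv1 features
resolveConv1Features <- function(minimodel, stimuli) {
  if (is(stimuli, "StimulusSet")) stimuli <- images(stimuli)
  if (length(dim(stimuli)) == 4L) return(stimuli)
  conv1Features(minimodel@conv1, stimuli)
}

#' Predicted firing rate of a minimodel
#'
#' Evaluation-mode forward pass: frozen conv1 features -> neuron-specific
#' depthwise spatial kernels -> 1x1 channel mix -> batch norm (running
#' statistics) -> ReLU -> factorized readout -> `ELU(z) + 1`.
#'
#' @param minimodel a [Minimodel-class].
#' @param stimuli a [StimulusSet-class], image array `(H, W, N)`, or
#'   precomputed conv1 features `(H', W', N, C1)`.
#' @return numeric vector of predicted rates, one per stimulus.
#' @export
minimodelPredict <- function(minimodel, stimuli) {
  a0 <- resolveConv1Features(minimodel, stimuli)
  r <- minimodel@readout
  mm_forward(a0, minimodel@conv2Spatial, minimodel@conv2Mix,
             minimodel@bnGamma, minimodel@bnBeta, minimodel@bnMean,
             minimodel@bnVar, r@wx, r@wy, r@wc, r@offset, bnEps,
             FALSE)$rate
}

# spatially pooled conv2 channel activations (N x M), eval mode
minimodelPooled <- function(minimodel, stimuli) {
  a0 <- resolveConv1Features(minimodel, stimuli)
  r <- minimodel@readout
  mm_forward(a0, minimodel@conv2Spatial, minimodel@conv2Mix,
             minimodel@bnGamma, minimodel@bnBeta, minimodel@bnMean,
             minimodel@bnVar, r@wx, r@wy, r@wc, r@offset, bnEps,
             TRUE)$pooled
}

# full stage-wise activations of a minimodel on a set of images.
# Returns a list of stages in fixed order; spatial stages are (H, W, N, C).
minimodelStages <- function(minimodel, stimuli) {
  if (is(stimuli, "StimulusSet")) stimuli <- images(stimuli)
  stopIfNot(length(dim(stimuli)) == 3L,
            "minimodelStages needs raw images (stage 1 is conv1)")
  layer <- minimodel@conv1@layers[[1L]]
  x <- cc_conv1_forward(stimuli, layer$kernels)
  x <- applyBatchNorm(x, layer, mode = "eval")
  conv1Act <- pmax(x, 0) * 1
  dim(conv1Act) <- dim(x)
  pooled1 <- cc_maxpool2(conv1Act)$y
  s2 <- cc_dwconv_forward(pooled1, minimodel@conv2Spatial)
  d <- dim(s2)
  u <- matrix(s2, ncol = d[4L]) %*% minimodel@conv2Mix
  m <- ncol(minimodel@conv2Mix)
  inv <- 1 / sqrt(minimodel@bnVar + bnEps)
  u <- sweep(u, 2L, minimodel@bnMean, `-`)
  u <- sweep(u, 2L, minimodel@bnGamma * inv, `*`)
  u <- sweep(u, 2L, minimodel@bnBeta, `+`)
  act2 <- pmax(u, 0)
  dim(act2) <- c(d[1L], d[2L], d[3L], m)
  r <- minimodel@readout
  pooledWxy <- pooledChannels(act2, r)
  z <- as.vector(pooledWxy %*% r@wc) + r@offset
  list(conv1 = conv1Act, pool = pooled1, conv2_spatial = s2,
       conv2_mix_relu = act2, pooled_wxy = pooledWxy,
       readout = elu(z) + 1)
}
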