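#' Poisson loss between predicted rates and observed responses
#'
#' `mean(rate - response * log(rate))`, the negative Poisson log-likelihood
#' up to response-only terms; the natural cost for non-negative event-count
#' responses.
#'
#' @param rate predicted rates, strictly positive.
#' @param response observed responses, same length.
#' @return scalar loss.
#' @export
poissonLoss <- function(rate, response) {
  stopIfNot(length(rate) == length(response), "length mismatch")
  stopIfNot(all(rate > 0), "predicted rates must be strictly positive")
  mean(rate - response * log(rate))
}

#' Hoyer-Square sparsity penalty
#'
#' `H_S(w) = (sum |w|)^2 / sum w^2`, the squared L1/L2 ratio. Scale-invariant,
#' equal to the number of nonzero entries for equal-magnitude vectors (1 for
#' a one-hot vector, k for k equal nonzeros), and minimized by sparse weight
#' patterns without shrinking surviving magnitudes. `H_S(0)` is defined as 0.
#'
#' @param w numeric weight vector.
#' @return scalar penalty.
#' @export
hoyerSquare <- function(w) {
  s2 <- sum(w^2)
  if (s2 == 0) return(0)
  sum(abs(w))^2 / s2
}

hoyerSquareGrad <- function(w) {
  s2 <- sum(w^2)
  if (s2 == 0) return(numeric(length(w)))
  s1 <- sum(abs(w))
  2 * s1 * sign(w) / s2 - 2 * (s1^2 / s2^2) * w
}

#' Training schedule and optimizer configuration
#'
#' The default schedule is four periods: 100 epochs at learning rate 1e-3,
#' then three periods of 30 epochs each with the learning rate divided by 3
#' at every period. Optimization uses decoupled-weight-decay Adam with
#' per-group decays: 0.1 for convolutional weights, 1.0 for `wx`/`wy`, and
#' 0.1 (`wcDecay`, population) or 0.2 (minimodel) for `wc`; batch-norm
#' parameters and the readout offset are not decayed.
#'
#' @param scheduleScale multiply every period's epoch count by this factor
#'   (rounded up, at least 1 epoch per period) while keeping the /3 learning-
#'   rate ladder; used for desk-scale reduced schedules.
#' @param baseLr initial learning rate.
#' @param batchSize stimuli per optimization step.
#' @param coreDecay,spatialDecay weight decay for convolution/mix kernels.
#' @param wxDecay,wcDecay weight decay for the readout groups.
#' @param lambda Hoyer-Square strength on `wc` (minimodels only). The
#'   effective strength is ramped linearly from 0 to `lambda` over the first
#'   schedule period so channels form before they are pruned, then held
#'   constant.
#' @param seed seed for initialization and batching.
#' @param checkInvariants assert readout non-negativity after every step.
#' @return a config list.
#' @export
trainConfig <- function(scheduleScale = 1, baseLr = 1e-3, batchSize = 64L,
                        coreDecay = 0.1, spatialDecay = coreDecay,
                        wxDecay = 1.0, wcDecay = 0.1, lambda = 0,
                        seed = 1L, checkInvariants = FALSE) {
  epochs <- pmax(1L, ceiling(c(100L, 30L, 30L, 30L) * scheduleScale))
  list(schedule = data.frame(epochs = epochs, lr = baseLr / 3^(0:3)),
       batchSize = as.integer(batchSize),
       decays = c(core = coreDecay, spatial = spatialDecay, wx = wxDecay,
                  wy = wxDecay, wc = wcDecay),
       lambda = lambda, seed = as.integer(seed),
       checkInvariants = isTRUE(checkInvariants))
}

# ---- decoupled-weight-decay Adam over a flat named list of arrays ----

adamInit <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adamStep <- function(par, grad, state, lr, decays,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    dec <- decays[[nm]]
    par[[nm]] <- par[[nm]] - lr * step - lr * dec * par[[nm]]
  }
  list(par = par, state = state)
}

epochLearningRates <- function(schedule) {
  rep(schedule$lr, schedule$epochs)
}

# R^2-style validation score: FEVE with zero noise variance, for
# single-presentation validation responses
validationScore <- function(pred, obs) {
  v <- stats::var(obs)
  if (!isTRUE(v > 0)) return(NA_real_)
  1 - mean((obs - pred)^2) / v
}

# ---- minimodel fitting -------------------------------------------------

#' Fit a minimodel to a single neuron
#'
#' Trains the neuron-specific part of a two-layer minimodel (depthwise
#' spatial conv2, 1x1 channel mix, batch norm, ReLU, factorized readout) on
#' frozen conv1 features, with a Poisson loss plus `lambda * H_S(wc)`
#' (Hoyer-Square, [hoyerSquare()]). `wx`/`wy` are clamped non-negative after
#' every optimizer step; the model snapshot with the best validation score
#' across epochs (including the initialization) is returned. Readout weights
#' are initialized from N(0, 0.01) (`wx`, `wy`) and N(0, 0.2) (`wc`).
#'
#' @param stimuli a [StimulusSet-class] with train/val splits.
#' @param responseSet a [ResponseSet-class] aligned to `stimuli`.
#' @param neuron column index of the neuron to fit.
#' @param conv1 the frozen 1-layer [ConvCore-class].
#' @param config a list from [trainConfig()] (use `lambda` there for the
#'   sparsity strength).
#' @param nOutputChannels conv2 output channels (default 64).
#' @param kernelSize conv2 spatial kernel size (default 9).
#' @param conv1Feats optional precomputed [conv1Features()] array for all
#'   images of `stimuli` (a major saving when fitting many neurons).
#' @return a fitted [Minimodel-class]; `@log` holds per-epoch training loss
#'   and validation score.
#' @export
fitMinimodel <- function(stimuli, responseSet, neuron = 1L, conv1,
                         config = trainConfig(wcDecay = 0.2),
                         nOutputChannels = 64L, kernelSize = 9L,
                         conv1Feats = NULL) {
  stopIfNot(kernelSize %% 2L == 1L, "kernelSize must be odd")
  if (is.null(conv1Feats)) conv1Feats <- conv1Features(conv1, stimuli)
  d <- dim(conv1Feats)
  H <- d[1L]; W <- d[2L]; C1 <- d[4L]
  M <- as.integer(nOutputChannels)
  split <- splitLabels(stimuli)
  pres <- presentationMap(responseSet)
  y <- responses(responseSet)[, neuron]
  trainRows <- which(split[pres$image] == "train")
  valRows <- which(split[pres$image] == "val" & pres$rep == 1L)
  stopIfNot(length(trainRows) > 0 && length(valRows) > 0,
            "need train and val presentations")
  valImgs <- pres$image[valRows]
  yVal <- y[valRows]
  a0Val <- conv1Feats[, , valImgs, , drop = FALSE]

  par <- withSeed(config$seed, list(
    k2 = xavierConv(kernelSize, kernelSize, 1L, C1),
    mix = matrix(runif(C1 * M, -sqrt(6 / (C1 + M)), sqrt(6 / (C1 + M))),
                 C1, M),
    gamma = rep(1, M), beta = rep(0, M),
    wx = pmax(rnorm(W, 0, 0.01), 0), wy = pmax(rnorm(H, 0, 0.01), 0),
    wc = rnorm(M, 0, 0.2), offset = 0))
  runMean <- rep(0, M)
  runVar <- rep(1, M)
  decays <- c(k2 = unname(config$decays["spatial"]),
              mix = unname(config$decays["core"]),
              gamma = 0, beta = 0, wx = unname(config$decays["wx"]),
              wy = unname(config$decays["wy"]),
              wc = unname(config$decays["wc"]), offset = 0)
  state <- adamInit(par)
  lambda <- config$lambda

  evalScore <- function() {
    out <- mm_forward(a0Val, par$k2, par$mix, par$gamma, par$beta, runMean,
                      runVar, par$wx, par$wy, par$wc, par$offset, bnEps,
                      FALSE)
    validationScore(out$rate, yVal)
  }
  warmupEpochs <- sum(config$schedule$epochs[1:2])

  # one optimization phase over the given epoch learning rates; wcMask (if
  # any) freezes pruned channel weights at exactly zero after every step
  runPhase <- function(par, state, runMean, runVar, lrs, lam, wcMask = NULL,
                       seedOffset = 0L, warmup = warmupEpochs) {
    best <- list(par = par, runMean = runMean, runVar = runVar,
                 score = local({
                   p0 <- par
                   out <- mm_forward(a0Val, p0$k2, p0$mix, p0$gamma, p0$beta,
                                     runMean, runVar, p0$wx, p0$wy, p0$wc,
                                     p0$offset, bnEps, FALSE)
                   validationScore(out$rate, yVal)
                 }), epoch = 0L)
    log <- data.frame(epoch = integer(0), lr = numeric(0),
                      trainLoss = numeric(0), valScore = numeric(0))
    final <- NULL
    for (ep in seq_along(lrs)) {
      ord <- withSeed(config$seed + seedOffset + 131L * ep,
                      sample(trainRows))
      nb <- max(1L, floor(length(ord) / config$batchSize))
      epochLoss <- 0
      lamEp <- lam * min(1, ep / warmup)
      for (b in seq_len(nb)) {
        rows <- ord[seq.int((b - 1L) * config$batchSize + 1L,
                            if (b == nb) length(ord)
                            else b * config$batchSize)]
        a0b <- conv1Feats[, , pres$image[rows], , drop = FALSE]
        st <- mm_step(a0b, y[rows], par$k2, par$mix, par$gamma, par$beta,
                      par$wx, par$wy, par$wc, par$offset, bnEps)
        if (!is.finite(st$loss))
          stop("minimodel training diverged (non-finite loss) at epoch ",
               ep, call. = FALSE)
        grad <- list(k2 = st$dk2, mix = st$dmix, gamma = st$dgamma,
                     beta = st$dbeta, wx = st$dwx, wy = st$dwy,
                     wc = st$dwc, offset = st$doffset)
        if (lamEp > 0) grad$wc <- grad$wc + lamEp * hoyerSquareGrad(par$wc)
        up <- adamStep(par, grad, state, lrs[ep], decays)
        par <- up$par
        state <- up$state
        par$wx <- pmax(par$wx, 0)
        par$wy <- pmax(par$wy, 0)
        if (!is.null(wcMask)) par$wc[!wcMask] <- 0
        if (config$checkInvariants)
          stopifnot(all(par$wx >= 0), all(par$wy >= 0))
        runMean <- (1 - bnMomentum) * runMean + bnMomentum * st$batch_mean
        nB <- length(rows) * H * W
        runVar <- (1 - bnMomentum) * runVar +
          bnMomentum * st$batch_var * nB / max(nB - 1L, 1L)
        epochLoss <- epochLoss + st$loss +
          if (lamEp > 0) lamEp * hoyerSquare(par$wc) else 0
      }
      out <- mm_forward(a0Val, par$k2, par$mix, par$gamma, par$beta,
                        runMean, runVar, par$wx, par$wy, par$wc,
                        par$offset, bnEps, FALSE)
      sc <- validationScore(out$rate, yVal)
      log <- rbind(log, data.frame(epoch = ep, lr = lrs[ep],
                                   trainLoss = epochLoss / nb,
                                   valScore = sc))
      if (!is.na(sc) && (is.na(best$score) || sc > best$score))
        best <- list(par = par, runMean = runMean, runVar = runVar,
                     score = sc, epoch = ep)
      final <- list(par = par, runMean = runMean, runVar = runVar,
                    score = sc, epoch = ep)
    }
    list(best = best, final = final, log = log)
  }

  main <- runPhase(par, state, runMean, runVar,
                   epochLearningRates(config$schedule), lambda)
  best <- main$best
  log <- main$log
  p <- best$par
  fineTuneLog <- NULL
  if (lambda > 0) {
    # Threshold-and-fine-tune, the standard pipeline of Hoyer-Square
    # pruning: take the *converged* (final-epoch) weights, where the penalty
    # has driven pruned channels to near-exact zero (Adam's normalized steps
    # leave them jittering at the final learning-rate scale), snap weights
    # below 1% of the largest magnitude to exact zero so the active-channel
    # count (|wc| > 1e-6) is well defined, then fine-tune the surviving
    # channels with the penalty off and the pruned weights frozen at zero,
    # selecting the best epoch of the fine-tune phase (its epoch 0 is the
    # snapped model itself).
    p <- main$final$par
    if (any(p$wc != 0)) {
      thr <- 0.01 * max(abs(p$wc))
      p$wc[abs(p$wc) < thr] <- 0
    }
    mask <- p$wc != 0
    ftSchedule <- config$schedule
    ftSchedule$epochs <- pmax(1L, ceiling(ftSchedule$epochs / 2))
    ft <- runPhase(p, adamInit(p), main$final$runMean, main$final$runVar,
                   epochLearningRates(ftSchedule), lam = 0,
                   wcMask = mask, seedOffset = 100003L)
    best <- ft$best
    p <- best$par
    fineTuneLog <- ft$log
  }
  Minimodel(conv1 = conv1, conv2Spatial = p$k2, conv2Mix = p$mix,
            bnGamma = p$gamma, bnBeta = p$beta, bnMean = best$runMean,
            bnVar = best$runVar,
            readout = FactorizedReadout(p$wx, p$wy, p$wc, p$offset),
            lambda = lambda,
            log = list(epochs = log, fineTune = fineTuneLog,
                       bestEpoch = best$epoch,
                       bestValScore = best$score, seed = config$seed))
}

#' Select the Hoyer-Square sparsity strength on pilot neurons
#'
#' Fits every pilot neuron at every candidate strength (plus `lambda = 0` as
#' the reference if absent) and returns the strength that minimizes the mean
#' active-channel count subject to the mean validation score staying within
#' 1% (relative) of the unregularized reference. Ties on the channel count go
#' to the largest feasible strength. When no candidate is feasible, 0 is
#' returned with a warning.
#'
#' @param candidateLambdas ascending candidate strengths.
#' @param stimuli,responseSet,conv1 as in [fitMinimodel()].
#' @param pilotNeurons indices of >= 2 pilot neurons.
#' @param config base [trainConfig()] (its `lambda` is overridden).
#' @param relTol allowed relative validation drop (default 0.01).
#' @param ... passed to [fitMinimodel()] (`nOutputChannels`, `conv1Feats`...).
#' @return selected strength, with attribute `"sweep"`: a data.frame of mean
#'   channel counts and validation scores per candidate.
#' @export
selectSparsityStrength <- function(candidateLambdas, stimuli, responseSet,
                                   pilotNeurons, conv1,
                                   config = trainConfig(wcDecay = 0.2),
                                   relTol = 0.01, ...) {
  stopIfNot(length(pilotNeurons) >= 2L, "need >= 2 pilot neurons")
  stopIfNot(!is.unsorted(candidateLambdas), "candidates must be ascending")
  lams <- unique(c(0, candidateLambdas))
  rows <- lapply(lams, function(lam) {
    cfg <- config
    cfg$lambda <- lam
    fits <- lapply(pilotNeurons, function(i)
      fitMinimodel(stimuli, responseSet, neuron = i, conv1 = conv1,
                   config = cfg, ...))
    data.frame(lambda = lam,
               meanChannels = mean(vapply(fits, nActiveChannels, 0L)),
               meanValScore = mean(vapply(fits, function(f)
                 f@log$bestValScore, 0)))
  })
  sweep <- do.call(rbind, rows)
  ref <- sweep$meanValScore[sweep$lambda == 0]
  feasible <- sweep$meanValScore >= ref - relTol * abs(ref)
  cand <- sweep[feasible & sweep$lambda %in% candidateLambdas, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no feasible sparsity strength; returning 0")
    return(structure(0, sweep = sweep))
  }
  cand <- cand[cand$meanChannels == min(cand$meanChannels), , drop = FALSE]
  structure(max(cand$lambda), sweep = sweep)
}
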