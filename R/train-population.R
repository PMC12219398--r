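# Population-model training: shared conv core + per-neuron factorized
# readouts, trained jointly with Poisson loss and decoupled weight decay.
# The forward/backward passes are orchestrated in R over the compiled
# convolution primitives; per-neuron minimodel fitting has its own fused
# compiled step (mm_step) since it is the throughput-critical path.

activationPrimeFromOutput <- function(a, activation) {
  switch(activation,
    elu = ifelse(a > 0, 1, a + 1),
    relu = as.numeric(a > 0),
    identity = rep_len(1, length(a)),
    stop("unknown activation: ", activation))
}

flipKernels <- function(k) {
  d <- dim(k)
  k[d[1L]:1L, d[2L]:1L, , drop = FALSE]
}

avgPool2Bwd <- function(gy, H, W) {
  d <- dim(gy)
  gx <- array(0, c(H, W, d[3L], d[4L]))
  g <- 0.25 * gy
  gx[c(TRUE, FALSE), c(TRUE, FALSE), , ] <- g
  gx[c(FALSE, TRUE), c(TRUE, FALSE), , ] <- g
  gx[c(TRUE, FALSE), c(FALSE, TRUE), , ] <- g
  gx[c(FALSE, TRUE), c(FALSE, TRUE), , ] <- g
  gx
}

bnForwardTrain <- function(pre, gamma, beta) {
  d <- dim(pre)
  C <- d[4L]
  u <- matrix(pre, ncol = C)
  mu <- colMeans(u)
  v <- colMeans(u^2) - mu^2
  inv <- 1 / sqrt(v + bnEps)
  y <- sweep(sweep(u, 2L, mu, `-`), 2L, gamma * inv, `*`)
  y <- sweep(y, 2L, beta, `+`)
  dim(y) <- d
  list(y = y, u = u, mu = mu, v = v, inv = inv)
}

bnBackward <- function(dY, u, mu, inv, gamma) {
  P <- nrow(u)
  xhat <- sweep(sweep(u, 2L, mu, `-`), 2L, inv, `*`)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dU <- sweep(dY, 2L, dbeta / P, `-`) -
    sweep(xhat, 2L, dgamma / P, `*`)
  dU <- sweep(dU, 2L, gamma * inv, `*`)
  list(dU = dU, dgamma = dgamma, dbeta = dbeta)
}

popInitParams <- function(cfg, nNeurons, H2, W2, seed) {
  core <- newConvCore(cfg, seed = seed)
  par <- list()
  for (l in seq_len(cfg$nLayers)) {
    par[[paste0("k", l)]] <- core@layers[[l]]$kernels
    if (l > 1L) par[[paste0("m", l)]] <- core@layers[[l]]$mix
    par[[paste0("g", l)]] <- core@layers[[l]]$gamma
    par[[paste0("b", l)]] <- core@layers[[l]]$beta
  }
  withSeed(seed + 17L, {
    for (i in seq_len(nNeurons)) {
      par[[paste0("wx", i)]] <- pmax(rnorm(W2, 0, 0.01), 0)
      par[[paste0("wy", i)]] <- pmax(rnorm(H2, 0, 0.01), 0)
      par[[paste0("wc", i)]] <- rnorm(cfg$channels[cfg$nLayers], 0, 0.01)
      par[[paste0("off", i)]] <- 0
    }
  })
  par
}

popDecays <- function(par, decays) {
  out <- numeric(length(par))
  names(out) <- names(par)
  for (nm in names(par)) {
    out[nm] <- if (grepl("^k1$", nm)) decays[["core"]]
    else if (grepl("^k", nm)) decays[["spatial"]]
    else if (grepl("^m", nm)) decays[["core"]]
    else if (grepl("^w[xy]", nm)) decays[["wx"]]
    else if (grepl("^wc", nm)) decays[["wc"]]
    else 0
  }
  out
}

# evaluation-mode forward through the core given flat params + running stats
popForwardEval <- function(par, runStats, cfg, imgs) {
  x <- NULL
  for (l in seq_len(cfg$nLayers)) {
    if (l == 1L) {
      pre <- cc_conv1_forward(imgs, par$k1)
    } else {
      s <- cc_dwconv_forward(x, par[[paste0("k", l)]])
      d <- dim(s)
      pre <- matrix(s, ncol = d[4L]) %*% par[[paste0("m", l)]]
      dim(pre) <- c(d[1L], d[2L], d[3L], ncol(par[[paste0("m", l)]]))
    }
    d <- dim(pre)
    u <- matrix(pre, ncol = d[4L])
    inv <- 1 / sqrt(runStats[[l]]$var + bnEps)
    y <- sweep(sweep(u, 2L, runStats[[l]]$mean, `-`), 2L,
               par[[paste0("g", l)]] * inv, `*`)
    y <- sweep(y, 2L, par[[paste0("b", l)]], `+`)
    a <- applyActivation(y, cfg$activation)
    dim(a) <- d
    x <- a
    if (l == 1L)
      x <- if (cfg$poolType == "max") cc_maxpool2(x)$y else avgPool2(x)
  }
  x
}

popPredictEval <- function(par, runStats, cfg, imgs, nNeurons, rate = TRUE) {
  f <- popForwardEval(par, runStats, cfg, imgs)
  vapply(seq_len(nNeurons), function(i) {
    r <- FactorizedReadout(par[[paste0("wx", i)]], par[[paste0("wy", i)]],
                           par[[paste0("wc", i)]], par[[paste0("off", i)]])
    readoutForward(f, r, rate = rate)
  }, numeric(dim(f)[3L]))
}

#' Train a population model (shared core + per-neuron readouts)
#'
#' Joint fitting of the convolutional core and all factorized readouts with
#' Poisson loss, decoupled-weight-decay Adam (per-group decays from
#' [trainConfig()]), the 4-period /3 learning-rate ladder, non-negativity
#' clamping of `wx`/`wy` after every step, and epoch-wise model selection on
#' the validation score (the initialization counts as epoch 0, so the
#' returned snapshot is never worse than it). Aborts with a diagnostic on a
#' non-finite loss.
#'
#' @param coreCfg a [coreConfig()] list (use `activation = "identity"`,
#'   `poolType = "avg"` for the LN model).
#' @param stimuli a [StimulusSet-class] with train/val splits.
#' @param responseSet a [ResponseSet-class] aligned to `stimuli`.
#' @param config a [trainConfig()] list.
#' @return a [PopulationModel-class]; `@log` has per-epoch losses and
#'   validation scores.
#' @export
trainPopulation <- function(coreCfg, stimuli, responseSet,
                            config = trainConfig()) {
  imgs <- images(stimuli)
  split <- splitLabels(stimuli)
  pres <- presentationMap(responseSet)
  Y <- responses(responseSet)
  nn <- ncol(Y)
  stopIfNot(nn >= 1, "need at least one neuron")
  trainRows <- which(split[pres$image] == "train")
  valRows <- which(split[pres$image] == "val" & pres$rep == 1L)
  stopIfNot(length(trainRows) > 0 && length(valRows) > 0,
            "need train and val presentations")
  valImgs <- imgs[, , pres$image[valRows], drop = FALSE]
  yVal <- Y[valRows, , drop = FALSE]
  L <- coreCfg$nLayers
  H2 <- dim(imgs)[1L] %/% 2L
  W2 <- dim(imgs)[2L] %/% 2L
  if (L == 1L) { Hr <- H2; Wr <- W2 } else { Hr <- H2; Wr <- W2 }
  par <- popInitParams(coreCfg, nn, Hr, Wr, config$seed)
  decays <- popDecays(par, config$decays)
  state <- adamInit(par)
  runStats <- lapply(seq_len(L), function(l)
    list(mean = rep(0, coreCfg$channels[l]), var = rep(1, coreCfg$channels[l])))

  evalScore <- function() {
    preds <- popPredictEval(par, runStats, coreCfg, valImgs, nn)
    mean(vapply(seq_len(nn), function(i)
      validationScore(preds[, i], yVal[, i]), 0), na.rm = TRUE)
  }
  best <- list(par = par, runStats = runStats, score = evalScore(),
               epoch = 0L)
  lrs <- epochLearningRates(config$schedule)
  logDf <- data.frame(epoch = integer(0), lr = numeric(0),
                      trainLoss = numeric(0), valScore = numeric(0))
  act <- coreCfg$activation

  for (ep in seq_along(lrs)) {
    ord <- withSeed(config$seed + 131L * ep, sample(trainRows))
    nb <- max(1L, floor(length(ord) / config$batchSize))
    epochLoss <- 0
    for (b in seq_len(nb)) {
      rows <- ord[seq.int((b - 1L) * config$batchSize + 1L,
                          if (b == nb) length(ord) else b * config$batchSize)]
      X <- imgs[, , pres$image[rows], drop = FALSE]
      B <- length(rows)
      # ---- forward with caches ----
      caches <- vector("list", L)
      x <- NULL
      for (l in seq_len(L)) {
        if (l == 1L) {
          pre <- cc_conv1_forward(X, par$k1)
          sIn <- NULL
        } else {
          sIn <- cc_dwconv_forward(x, par[[paste0("k", l)]])
          d <- dim(sIn)
          pre <- matrix(sIn, ncol = d[4L]) %*% par[[paste0("m", l)]]
          dim(pre) <- c(d[1L], d[2L], d[3L], ncol(par[[paste0("m", l)]]))
        }
        bn <- bnForwardTrain(pre, par[[paste0("g", l)]],
                             par[[paste0("b", l)]])
        a <- applyActivation(bn$y, act)
        dim(a) <- dim(bn$y)
        cache <- list(input = x, s = sIn, u = bn$u, mu = bn$mu, v = bn$v,
                      inv = bn$inv, a = a)
        if (l == 1L) {
          if (coreCfg$poolType == "max") {
            mp <- cc_maxpool2(a)
            x <- mp$y
            cache$poolIdx <- mp$idx
            cache$preH <- dim(a)[1L]
            cache$preW <- dim(a)[2L]
          } else {
            x <- avgPool2(a)
            cache$preH <- dim(a)[1L]
            cache$preW <- dim(a)[2L]
          }
        } else x <- a
        caches[[l]] <- cache
      }
      f <- x  # final features (Hr, Wr, B, C)
      dOut <- dim(f)
      fMat <- matrix(f, nrow = dOut[1L] * dOut[2L])
      dF <- matrix(0, nrow(fMat), ncol(fMat))
      loss <- 0
      grad <- lapply(par, function(p) p * 0)
      for (i in seq_len(nn)) {
        wx <- par[[paste0("wx", i)]]
        wy <- par[[paste0("wy", i)]]
        wc <- par[[paste0("wc", i)]]
        off <- par[[paste0("off", i)]]
        s <- as.vector(outer(wy, wx))
        pooled <- matrix(s %*% fMat, nrow = B)
        z <- as.vector(pooled %*% wc) + off
        rate <- elu(z) + 1
        rate <- pmax(rate, 1e-12)
        yObs <- Y[rows, i]
        loss <- loss + mean(rate - yObs * log(rate)) / nn
        dz <- (1 - yObs / rate) * eluPrime(z) / (B * nn)
        grad[[paste0("wc", i)]] <- as.vector(crossprod(pooled, dz))
        grad[[paste0("off", i)]] <- sum(dz)
        dpooled <- dz %o% wc
        g2 <- matrix(fMat %*% as.vector(dpooled), dOut[1L], dOut[2L])
        grad[[paste0("wx", i)]] <- as.vector(wy %*% g2)
        grad[[paste0("wy", i)]] <- as.vector(g2 %*% wx)
        dF <- dF + s %o% as.vector(dpooled)
      }
      if (!is.finite(loss))
        stop("population training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      # ---- backward through the core ----
      dA <- dF
      dim(dA) <- dOut
      for (l in seq.int(L, 1L)) {
        cache <- caches[[l]]
        if (l == 1L) {
          dA <- if (coreCfg$poolType == "max")
            cc_maxpool2_bwd(dA, cache$poolIdx, cache$preH, cache$preW)
          else avgPool2Bwd(dA, cache$preH, cache$preW)
        }
        dAp <- dA * activationPrimeFromOutput(cache$a, act)
        dim(dAp) <- dim(cache$a)
        dY <- matrix(dAp, ncol = dim(cache$a)[4L])
        bb <- bnBackward(dY, cache$u, cache$mu, cache$inv,
                         par[[paste0("g", l)]])
        grad[[paste0("g", l)]] <- bb$dgamma
        grad[[paste0("b", l)]] <- bb$dbeta
        dPre <- bb$dU
        if (l == 1L) {
          dPreA <- dPre
          dim(dPreA) <- dim(cache$a)
          grad$k1 <- cc_conv1_gradk(X, dPreA, dim(par$k1)[1L],
                                    dim(par$k1)[2L])
        } else {
          mixName <- paste0("m", l)
          kName <- paste0("k", l)
          grad[[mixName]] <- crossprod(matrix(cache$s,
                                              ncol = nrow(par[[mixName]])),
                                       dPre)
          dS <- dPre %*% t(par[[mixName]])
          dim(dS) <- dim(cache$s)
          grad[[kName]] <- cc_dwconv_gradk(cache$input, dS,
                                           dim(par[[kName]])[1L],
                                           dim(par[[kName]])[2L])
          dA <- cc_dwconv_forward(dS, flipKernels(par[[kName]]))
        }
        # running statistics
        nB <- nrow(cache$u)
        runStats[[l]]$mean <- (1 - bnMomentum) * runStats[[l]]$mean +
          bnMomentum * cache$mu
        runStats[[l]]$var <- (1 - bnMomentum) * runStats[[l]]$var +
          bnMomentum * cache$v * nB / max(nB - 1L, 1L)
      }
      up <- adamStep(par, grad, state, lrs[ep], decays)
      par <- up$par
      state <- up$state
      for (i in seq_len(nn)) {
        par[[paste0("wx", i)]] <- pmax(par[[paste0("wx", i)]], 0)
        par[[paste0("wy", i)]] <- pmax(par[[paste0("wy", i)]], 0)
        if (config$checkInvariants)
          stopifnot(all(par[[paste0("wx", i)]] >= 0),
                    all(par[[paste0("wy", i)]] >= 0))
      }
      epochLoss <- epochLoss + loss
    }
    sc <- evalScore()
    logDf <- rbind(logDf, data.frame(epoch = ep, lr = lrs[ep],
                                     trainLoss = epochLoss / nb,
                                     valScore = sc))
    if (!is.na(sc) && (is.na(best$score) || sc > best$score))
      best <- list(par = par, runStats = runStats, score = sc, epoch = ep)
  }
  buildPopulationModel(coreCfg, best$par, best$runStats, nn,
                       list(epochs = logDf, bestEpoch = best$epoch,
                            bestValScore = best$score, val = logDf$valScore,
                            seed = config$seed))
}

buildPopulationModel <- function(cfg, par, runStats, nNeurons, log) {
  layers <- lapply(seq_len(cfg$nLayers), function(l) {
    list(kernels = par[[paste0("k", l)]],
         mix = if (l > 1L) par[[paste0("m", l)]] else NULL,
         gamma = par[[paste0("g", l)]], beta = par[[paste0("b", l)]],
         runMean = runStats[[l]]$mean, runVar = runStats[[l]]$var)
  })
  core <- new("ConvCore", config = cfg, layers = layers)
  readouts <- lapply(seq_len(nNeurons), function(i)
    FactorizedReadout(par[[paste0("wx", i)]], par[[paste0("wy", i)]],
                      par[[paste0("wc", i)]], par[[paste0("off", i)]]))
  new("PopulationModel", core = core, readouts = readouts, log = log)
}

#' Predicted rates of a population model
#'
#' Evaluation-mode forward pass through the core and every readout.
#'
#' @param model a [PopulationModel-class].
#' @param stimuli a [StimulusSet-class] or image array.
#' @return matrix `(n_images, n_neurons)` of predicted rates.
#' @export
populationPredict <- function(model, stimuli) {
  f <- coreForward(model@core, stimuli)
  vapply(model@readouts, function(r) readoutForward(f, r),
         numeric(dim(f)[3L]))
}
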