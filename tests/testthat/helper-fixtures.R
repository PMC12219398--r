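# Shared fixtures, built lazily and cached for the whole test run.
# Geometries are deliberately small; the acceptance tests build their own
# full-scale fixture (helper-acceptance.R).

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# 60 small natural images with splits, plus a 16-kernel conv1 bank
tinyWorld <- function() fixture("tinyWorld", function() {
  stim <- generateNaturalImages(60, 32, 48, seed = 101, nTest = 10,
                                valFraction = 0.15, testRepeats = 4)
  conv1 <- makeConv1Bank(stim, seed = 102)
  feats <- conv1Features(conv1, stim)
  neurons <- makeGroundTruthPopulation(conv1, stim, nNeurons = 3,
                                       channelsPerNeuron = 3, seed = 103,
                                       conv1Feats = feats)
  list(stim = stim, conv1 = conv1, feats = feats, neurons = neurons)
})

# small texture set (4 categories)
tinyTextures <- function() fixture("tinyTextures", function() {
  generateTextureSet(4, 21, 32, seed = 111, testRepeats = 3)
})

# texture world matching the model geometry of tinyWorld (32 x 48 images)
textureWorld <- function() fixture("textureWorld", function() {
  tw <- tinyWorld()
  tx <- generateTextureSet(3, 24, c(32, 48), seed = 121, parentSize = 160,
                           testFraction = 0.25, testRepeats = 4)
  tx <- matchAmplitudeSpectra(tx)
  txFeats <- conv1Features(tw$conv1, tx)
  rs <- simulateResponses(tw$neurons, tx, seed = 122, conv1Feats = txFeats)
  list(tw = tw, tx = tx, txFeats = txFeats, rs = rs)
})

# small bank shared across Gabor tests
gaborFixture <- function() fixture("gaborBank", function() {
  h <- 32L; w <- 64L
  bank <- buildGaborBank(h, w, centers = rbind(c(16, 24), c(16, 40)),
                         freqs = c(0.25, 0.5, 1), alphas = c(2.5, 3.5, 4.5),
                         betas = c(1, 1.5))
  stim <- generateNaturalImages(360, h, w, seed = 71, nTest = 60,
                                valFraction = 0.1)
  list(bank = bank, stim = stim, h = h, w = w)
})

# deterministic repeat matrix with planted signal/noise variances
plantedRepeats <- function(I, J, s2, v, seed) {
  withSeed(seed, {
    sig <- rnorm(I, 0, sqrt(s2))
    matrix(sig, I, J) + matrix(rnorm(I * J, 0, sqrt(v)), I, J)
  })
}

withSeed <- miniV1:::withSeed

# explicit-sum oracle for FEV: no vectorized shortcuts
fevOracle <- function(r) {
  vals <- c()
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    vals <- c(vals, r[i, j])
  }
  gm <- sum(vals) / length(vals)
  vt <- 0
  for (v in vals) vt <- vt + (v - gm)^2
  vt <- vt / (length(vals) - 1)
  noise <- 0
  for (i in seq_len(nrow(r))) {
    mi <- sum(r[i, ]) / ncol(r)
    vi <- 0
    for (j in seq_len(ncol(r))) vi <- vi + (r[i, j] - mi)^2
    noise <- noise + vi / (ncol(r) - 1)
  }
  noise <- noise / nrow(r)
  (vt - noise) / vt
}

# explicit-sum oracle for pairwise FECV over exactly two categories
fecvPairOracle <- function(a, b) {
  all <- c(a, b)
  gm <- sum(all) / length(all)
  tot <- 0
  for (v in all) tot <- tot + (v - gm)^2
  tot <- tot / (length(all) - 1)
  wv <- function(x) {
    m <- sum(x) / length(x)
    s <- 0
    for (v in x) s <- s + (v - m)^2
    s / (length(x) - 1)
  }
  resid <- (wv(a) + wv(b)) / 2
  (tot - resid) / tot
}
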