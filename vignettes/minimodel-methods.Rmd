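---
title: "Simplified encoding minimodels of V1: models, metrics and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified encoding minimodels of V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

A visual encoding model predicts the trial-averaged response of a neuron to
an arbitrary image. miniV1 implements a deliberately small family of such
models for primary visual cortex:

* a **population model**: a convolutional "core" shared by all neurons
  (1-4 layers; by default 16 kernels of size 25 in layer 1 and a wide
  depth-separable second layer), followed by one **factorized readout** per
  neuron;
* per-neuron **minimodels**: the first layer is frozen and shared, the
  second layer is neuron-specific (a channel-wise 9x9 spatial kernel per
  conv1 channel, a 1x1 mix into 64 output channels, batch normalization,
  ReLU), and the readout's channel weights are made sparse with a
  Hoyer-Square penalty, so each neuron ends up using only a handful of
  second-layer feature maps.

Every core layer is convolution (no bias) -> batch normalization ->
pointwise nonlinearity, with a single 2x2 max pool after layer 1.
Convolutions use "same" zero padding so feature maps keep the stimulus
resolution apart from the one pooling step; this is what makes the readout
pooling profiles directly interpretable as maps over visual space.

The factorized readout is a rank-1 spatial profile: non-negative vectors
`wy` over rows and `wx` over columns (clamped above zero after every
optimizer step), combined with a signed channel vector `wc`:

```
z = sum_c wc[c] * sum_{y,x} wy[y] wx[x] F[y,x,c] + offset
rate = ELU(z) + 1
```

The output map `ELU(z) + 1` keeps rates strictly positive as required by the
Poisson likelihood. The learnable scalar offset sits *inside* the map; an
additive offset after the map could make rates non-positive, which is the
one place we deviate from a literal readout-plus-offset formulation.

# Fitting

Training minimizes the Poisson loss `mean(rate - response * log(rate))` with
decoupled-weight-decay Adam. Weight-decay groups follow the published
recipe: 0.1 on convolutional and 1x1 weights, 1.0 on `wx`/`wy`, 0.1 on `wc`
for population models and 0.2 for minimodels; batch-norm parameters and the
offset are not decayed. The schedule has four periods — 100 epochs at
learning rate 1e-3, then three periods of 30 epochs with the rate divided
by 3 each period — and the returned model is the epoch with the best
validation score, the initialization included, so model selection can never
return something worse than where it started. `trainConfig(scheduleScale =)`
scales every period's epoch count while preserving the /3 ladder; the
package's tests and examples run at scales 0.02-0.2. Validation responses
are single presentations, so the validation score is the FEVE formula with
the noise-variance term at zero (an R^2 against the validation responses).

Batch size defaults to 64 stimuli; desk-scale fits in this package use 16,
which at ~1,000 training images gives Adam enough steps per period both to
fit and — with the sparsity penalty — to prune (pruning depth and fit
quality are step-count limited at reduced schedules). Batch normalization
uses batch statistics during training and running averages (momentum 0.1)
for all reported predictions, which makes evaluation deterministic.

## Sparsity and the number of second-layer channels

The Hoyer-Square penalty `H_S(w) = (sum|w|)^2 / sum(w^2)` is scale
invariant and equals the count of nonzero entries for equal-magnitude
vectors, so `loss + lambda * H_S(wc)` directly pressures the number of used
channels rather than their magnitudes. Two desk-scale properties of this
penalty under Adam are worth knowing:

* Adam normalizes gradient magnitudes per parameter, so once the penalty
  dominates a weight's gradient the pruning *speed* saturates in `lambda`;
  what controls the depth of pruning is mainly the number of optimizer
  steps. Very short schedules prune less than longer ones at the same
  `lambda`.
* pruned weights end up oscillating around zero at the scale of the final
  learning rate rather than at exactly zero. After the best epoch is
  selected, weights below 1% of the largest `|wc|` are therefore set to
  exactly zero, and a channel counts as active when `|wc| > 1e-6`. The 1%
  snap threshold sits in the wide gap between the surviving weights
  (~0.05-0.5) and the oscillation floor (~1e-4) and is documented here as
  part of the counting rule.

Two further optimization choices make sparse fits reliable at reduced
schedules. The effective strength ramps linearly from 0 to `lambda` over
the first two schedule periods, so second-layer features form (and the
learning rate partly anneals) before pruning decisions are made; and after the exact-zero snap the surviving channels are fine-tuned
with the penalty off and the pruned weights frozen at zero, re-running the
four-period schedule at half the epoch counts with epoch-best selection.
Threshold-and-fine-tune is the standard pipeline of Hoyer-Square network
pruning; without it, a fraction of fit seeds returns sparse solutions whose
surviving channels never recover the unpenalized validation score within a
short schedule.

`selectSparsityStrength()` implements the published selection rule: fit a
small pilot set of neurons at each candidate strength and keep the strength
that minimizes the mean active-channel count subject to the mean validation
score staying within 1% (relative) of the unpenalized reference.

# Metrics

For repeat-structured responses `r[i, j]` (image i, repeat j):

* **FEV** = `(Var[r] - s2_noise) / Var[r]`, with `s2_noise` the mean over
  images of the across-repeat variance — the fraction of response variance
  attributable to the stimulus. All variances use the unbiased (n-1)
  normalization; images with a single repeat contribute to `Var[r]` but not
  to the noise term. Neurons enter performance summaries when FEV > 0.15
  (strict).
* **FEVE** = `1 - (MSE - s2_noise) / (Var[r] - s2_noise)` for per-image
  model predictions — the fraction of the *explainable* variance the model
  captures.
* **FECV** applies the same decomposition to texture categories: for each
  pair of categories, the pooled total variance splits into the mean
  within-category variance and their difference, and FECV is the ratio of
  that category variance to the total, averaged over all category pairs.
  Finite-sample estimates can be negative and are deliberately not clipped;
  degenerate pairs (zero total variance) are skipped with a message.

**Pooling diameter** smooths `wx` and `wy` with a Gaussian of 3 samples
(kernel truncated at 4 sigma and renormalized, reflecting edges), measures
each full width at half maximum by linear interpolation between the
outermost half-max crossings, converts to degrees of visual angle, and
returns the geometric mean of the two widths. Readouts live on the 2x-pooled
feature grid, so the degrees-per-sample argument is the stimulus
pixel-to-degree scale times 2. For a Gaussian profile of width sigma the
measured diameter is `2.3548 * sqrt(sigma^2 + 9)` samples, which the tests
use as a closed-form check.

**Input diversity** is the mean pairwise Pearson correlation among the
`W_xy`-pooled activations of the channels with positive `wc` — a measure of
how redundant a neuron's excitatory inputs are.

# The synthetic-data module

Every fitting and metric path in the package is exercised on synthetic data
whose statistical structure matches what the estimators assume.

* **Naturalistic images**: Gaussian noise shaped to a power-law amplitude
  spectrum (`1/f` by default), zero mean (the DC bin is zeroed exactly) and
  unit variance per image, at the working geometry of 64 x 128 px and
  1 degree per pixel — the cropped-screen geometry of mouse experiments
  rounded to even dimensions so the single 2x2 pool is clean. Test images
  are repeated (10 repeats by default) and train/validation splits follow
  the 90/10 convention.
* **Texture categories**: one procedural parent texture per category —
  band-pass noise with a category-specific spatial-frequency band, a mildly
  anisotropic orientation band, and a category-specific pointwise power
  nonlinearity that sets higher-order "sparseness" statistics. Exemplars
  are random crops with modest rotation (+-20 degrees) and scale (0.85-1.2)
  jitter; each category splits 6:1 into train and test exemplars (300/50 at
  the published 350). The orientation band is broad (pi/4) by default on
  purpose: with narrowly oriented parents, category identity lives almost
  entirely in orientation, the category preferences of an orientation-tuned
  filter bank become anti-aligned across channels, and summing channels in
  a readout can only destroy category signal. With broad bands, category
  identity is carried by scale and higher-order statistics that modulate
  energy-type channels coherently — the regime in which pooling diverse
  inputs *increases* invariance, which is the phenomenon the invariance
  analyses measure. Natural photographic textures (rocks, grass, bark) are
  of this coherent kind.
* **Spectrum matching** removes the low-level cues: each image's Fourier
  amplitudes are rescaled so every category's mean amplitude spectrum
  equals the grand average (phases untouched), then per-category pixel
  means and standard deviations are set to 0 and 1. The two constraints
  interact: the per-category standardization rescales that category's
  spectra uniformly, and categories with different amplitude dispersion
  (different higher-order statistics) cannot satisfy both exactly. The
  moment step therefore leaves a small (~1e-2 at desk scale) residual in
  the matched spectra; `momentAdjust = FALSE` gives exactly matched spectra
  instead. This residual is a property of the estimator pair, not of the
  implementation.
* **Ground-truth neurons** are minimodels with known parameters: smooth
  random depthwise kernels, a sparse signed 1x1 mix into a small number of
  output channels, batch-norm statistics calibrated on a reference stimulus
  set, a Gaussian readout at a random center (width drawn per neuron),
  channel weights that are positive with probability 0.7, a readout scaled
  to unit variance and centered slightly positive (mean z = 0.3), and a
  gain set so the mean expected count is 2 events per presentation. At that
  operating point the Poisson-noise FEV of a typical neuron is near 0.5,
  the regime of reliably stimulus-driven cortical neurons. Responses are
  Poisson draws per presentation (the published noise model for model
  neurons); the noiseless limit returns expected rates, which is what the
  parameter-recovery tests use.
* **Noise calibration**: for Poisson noise the expected FEV at gain g has
  the closed form `g*Var[r] / (g*Var[r] + mean[r])` per neuron, monotone in
  g, so matching a target mean FEV is a bisection on log-gain, resolved to
  0.1% by default.

What the synthetic module does *not* emulate: calcium dynamics and
deconvolution artifacts, eye movements, behavioral modulation, and the
non-Poisson, correlated trial-to-trial variability of real recordings.
Passing the recovery tests therefore shows that the estimators and fitting
machinery are correct and well calibrated under their own assumptions — not
that real V1 neurons reach any particular FEVE.

# Numerical choices

* Convolutions are exact "same"-padded cross-correlations (compiled,
  channels-last layout); the depthwise + 1x1 decomposition of later layers
  is both the published architecture and what makes per-neuron fits cheap.
* Batch-norm epsilon is 1e-5, running-average momentum 0.1.
* Adam uses the common (0.9, 0.999) betas; weight decay is decoupled.
* Rates are clamped at 1e-12 inside the Poisson loss to guard underflow of
  `exp(z)` for very negative readouts.
* Half-max widths use the outermost crossings; multi-modal profiles are
  therefore measured across their full extent.
* Degenerate inputs (zero total variance, all-zero readouts, fewer than two
  positive channels, single-repeat images) return `NA` with a warning
  rather than a number.

# Problem sizes used by the tests and the acceptance script

Parameter-recovery runs fit 16-64 minimodels to neurons generated from
16-4 ground truth at the working 64 x 128 geometry with 1,500 images
(1,215 train / 135 validation / 150 test with repeats), schedule scale
0.15, batch 16, three fit seeds. The sparsity sweep runs two pilot neurons
on a 600-image set over candidate strengths 0.03 and 0.1 at the same
optimizer settings; the one-percent validation bound of the selection rule
is applied to the mean over fits, the scale at which it is defined (single
fits carry about one percent of optimizer noise at these schedules). Population-model
recovery uses a compact 8-16 core (kernels 13/7) on 36 x 52 images, which
preserves every architectural element while keeping joint core training
affordable. The invariance analyses use 100 ground-truth neurons with
pooling widths drawn from 2-10 feature samples and 4 spectrum-matched
texture categories of 40 exemplars. These sizes are the package's own
desk-scale study conditions; they are stated here so results can be
reproduced exactly.

# Known limitations

* Depth of Hoyer-Square pruning depends on schedule length (see above);
  very large penalties do not collapse a model to a single channel within a
  short schedule, they merely saturate the pruning speed.
* The population trainer is orchestrated in R over compiled kernels and is
  meant for compact cores; the per-neuron minimodel path is the optimized
  one.
* The dataset and checkpoint containers are validated single-file RDS
  schemas; they are self-describing within R but not language-neutral.
* Gabor-model frequency is parameterized in cycles per envelope size
  (wavelength `alpha/f` px), which keeps every printed grid point
  representable at the working resolutions; filter centers default to the
  image center and are configurable, since the published grid size admits
  more than one center convention.
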