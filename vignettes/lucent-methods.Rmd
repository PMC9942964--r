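---
title: "Methods: a synthetic test bed for layer-wise translucency probing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic test bed for layer-wise translucency probing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

Translucent materials — soap, skin, wax — owe their appearance to light
scattering beneath the surface. Human observers judge translucency reliably
across large changes of shape, body color and illumination, and one
productive way to study how they do it is to probe the layer-wise latent
space of a style-based image generator: in such models, coarse layers come
to control object shape, intermediate layers the material appearance, and
fine layers the body color. One can then train per-layer linear classifiers
that separate opaque from translucent exemplars, correlate their
normalised-distance predictions with human ratings layer by layer, edit
images along the boundary normal, and extract translucency-diagnostic image
kernels from the generator's mid-resolution intermediate outputs.

`lucent` rebuilds that whole analysis chain at desk scale, with the one
substitution that makes it testable: the GPU-trained generator and its photo
dataset are replaced by an *analytic* stand-in whose ground truth is known
exactly. Every downstream statistic — probe accuracy profiles, tuning-curve
peaks, edit selectivity, ICA kernel structure, psychophysical summaries —
can therefore be checked against the factors that actually generated the
stimuli.

## The synthetic scene and its factors

A stimulus is a soap-like blob on a light background, described by
`scene_factors`:

* a closed contour, `r(theta) = 0.62 (1 + sum_k a_k cos(k theta + phi_k))`
  with harmonics `k = 2..5` (amplitudes up to 0.09 at `k = 2`, weaker at
  higher `k`);
* an orientation (radians) — see the gauge note below;
* the translucency factor `tau` in `[0, 1]`, the quantity every analysis
  ultimately targets;
* a body color in RGB, bounded away from black so chromaticity is always
  defined;
* a lighting category (backlight / partial-front / side / diffuse, default
  frequencies 44 / 8 / 40 / 8 percent, matching the approximate mix of the
  emulated photo collection) with a continuous azimuth jitter, and a
  backlight strength in `[0, 1]`.

The two material classes are class-conditional truncated Gaussians over
`tau`: milky centred at 0.25, glycerin at 0.75 (both SD 0.12), with supports
`[0, 0.5 + overlap]` and `[0.5 - overlap, 1]`. The default `overlap = 0.1`
keeps a small positive Bayes error; `overlap = 0` makes the classes exactly
separable in `tau`, which several tests exploit.

### The renderer and its cues

`render_scene()` composes an opaque and a translucent component inside the
object mask and blends them with weight

```
w_t = tau * (0.75 + 0.25 * backlight_strength)
```

monotone in both factors. The opaque component is *purely multiplicative*
diffuse shading of the contour's implied relief — this guarantees constant
chromaticity inside the mask, so the edge-band chromatic-gradient statistic
(`glow_statistic()`) is exactly zero at `tau = 0`. The translucent component
adds the cues the analysis is designed to find: an inner glow falling off
with interior depth (decay scale a quarter of the local radius), a
low-amplitude hue/saturation gradient along the light axis, a softened and
weakened cast shadow, and a chromatic caustic opposite the light.
Backlight strength additionally dims the ambient background, giving that
factor a direct image signature.

Three renderer choices deserve explanation:

* **Cues are edge-localised.** An early version let `tau` shift the whole
  interior brightness. That makes translucency a dominant direction of raw
  pixel variance, and unsupervised pixel embeddings (t-SNE/MDS) then predict
  ratings nearly as well as the latent probe — the opposite of the
  behaviour the control analysis is supposed to exhibit, and also the
  opposite of how translucency behaves in photographs, where it lives in
  mid-scale features (glowing edges, inner glow) rather than in global
  brightness. The final renderer keeps the far interior close to the opaque
  brightness and concentrates the `tau` signature near the silhouette.
* **The glow is chromatic and luminance-matched.** The inner glow is
  dye-filtered light: a zero-sum (luminance-neutral) boost toward the
  saturated body color, and the translucent base level `0.71 + 0.06 bl`
  matches the opaque shading mean (~0.74). Translucency is therefore
  carried by chroma and spatial structure rather than by a brightness
  offset — which is also what makes the top translucency-contrast ICA
  kernel chromatic, as the feature-discovery analysis expects.
* **The backlight gain on the blend weight is mild (0.75–1.0).** A strong
  multiplicative `tau x backlight` interaction cannot be inverted by any
  linear pixel encoder; with the mild gain the material factor stays
  approximately linearly readable, which the image-encoder recovery
  contract (held-out `tau` error below 0.05) requires.

### Orientation is a gauge freedom

Rotating the object is the same image operation as shifting all contour
phases, so orientation and object-frame phases are not separately
identifiable from images — exactly as an unsupervised generator would
entangle them. The factor vector therefore stores the contour in
*image-frame* rectangular Fourier coefficients (`ca_k = a_k cos phi'_k`,
`cb_k = -a_k sin phi'_k`, with orientation folded into `phi'`), and both
angles (orientation, light azimuth) appear as cos/sin pairs. This keeps the
factor space a box, makes affine encoding exact, and removes wraparound
discontinuities that would otherwise defeat linear recovery checks.

## The analytic generator

`generator_config()` fixes `L = 18` layers of width `d = 16` (the layer
count and the early 1–6 / middle 7–9 / late 10–18 grouping mirror the
full-scale convention so that every layer index used downstream keeps its
meaning; the width is a scaled-down default, configurable up to 512). Each
group `g` owns an affine map `f_g = s * A_g w_g + b_g` with orthonormal rows
`A_g` over the group's concatenated rows:

* early -> contour coefficients and light-azimuth pair (12 factors),
* middle -> `tau` and backlight strength (2 factors),
* late -> body color and a fine multiplicative surface texture (4 factors).

`signal_scale = 0.25` maps the unit factor box to latent excursions of
about ±2, and nuisance directions (the null space of `A_g`) are filled with
seeded Gaussian noise of SD 0.25. The nuisance dimensions exist so probes
must ignore irrelevant directions; their SD, together with the signal
scale, sets the per-layer probe SNR (middle-layer CV accuracy around
0.95–0.99 at n = 1000, chance elsewhere). Factor readout is hard-clamped,
so decoding is a total function even for extreme codes.

`decode()` exposes three renders coarse-to-fine — a 16 px shape-only
render, a 64 px material render with neutral body color (the scale at which
translucency cues are established), and the full render — mirroring the
intermediate per-resolution outputs of a progressive synthesis network.

The image encoder is deliberately the simplest thing that satisfies its
contract: ridge regression from downsampled pixels (default 32 px) to the
latent matrix, with a per-sample penalty so duplicated training pairs do
not change the fit. Held-out recovery at the default sizes: mean `tau`
error about 0.03, per-group factor-subspace cosine similarity above 0.99.

## Probing, predictions, and the tuning curve

`train_layer_boundaries()` fits one linear max-margin classifier per layer
slice (squared-hinge primal, deterministic BFGS — no solver randomness).
`C` is selected by stratified nested cross-validation, 5 outer x 3 inner
folds, over 7 log-spaced points in `[0.001, 0.1]`; near-ties resolve to the
smallest `C` (one-standard-error rule), favouring the stronger
regularisation the protocol intends. Fold counts are a package choice; the
protocol only fixes the `C` range.

Two sign conventions coexist deliberately:

* the stored boundary normal is oriented so the milky (opaque) class is on
  the **positive** side — that is the editing convention (positive steps
  make the object more opaque);
* `predict_translucency()` reports the min-max-normalised signed distance
  toward the **translucent** side, so the prediction is a translucency
  score and correlates positively with translucency ratings. Using the raw
  milky-positive distance would flip every tuning-curve correlation
  negative while leaving its shape intact.

Normalisation bounds are fixed on the evaluation set by
`calibrate_boundary()` (whether the original protocol normalised over the
training or evaluation set is unstated; the bounds are stored in the model
so prediction is a pure function and the choice is auditable).

The pixel-space controls embed train + eval images jointly and run the same
linear-probe protocol in the embedding. t-SNE uses the exact (non-tree)
gradient, so the output dimensionality is unrestricted; the default
embedding dimension is 16 (the full-scale protocol's 512 is available but
slow). MDS is metric stress-majorisation (SMACOF) from a seeded random
start with the protocol's 300-iteration cap — the iterative method the
protocol describes, not closed-form classical scaling; the distinction
matters because the iterative embedding at finite iteration count is what
degrades low-variance directions such as the material factor.

## Editing

`edit_along_normal()` moves a single layer's row along the unit boundary
normal (default grid -3..3). Because shape is read only from early rows,
middle-layer edits provably preserve the mask (IoU exactly 1), move the
`tau` readout monotonically (decreasing along the positive, opaque
direction) and leave body color fixed; late-layer edits leave the material
readout inside clamp tolerance. `evaluate_edit()` reports the per-step
readouts and verdicts — an executable form of the selectivity matrix.

## ICA feature discovery

`build_high_translucency_set()` implements the middle-layer swap: the 40
top-rated images are targets, 40 further images join them as sources, and
every ordered source-target pair with source != target is decoded, keeping
the 64 px material-scale intermediate. Self-pairs are excluded because the
printed pair count (3160 = 80 x 40 - 40) is only consistent with that
reading. Patches (default 10 per image, 24 px, after bilinear upsampling to
512 px; the interpolation method is unstated in the protocol, bilinear is
the package choice) feed a symmetric fixed-point ICA (logcosh contrast,
PCA whitening to K components, seeded initial rotation). Kernels are the
unit-normalised mixing columns, ordered by a negentropy proxy, sign-fixed
so the largest-magnitude coefficient is positive. `classify_kernels()`
labels chromaticity by the fraction of the *mean-removed* kernel's energy
lying in channel deviations from the pixelwise channel mean (threshold
0.2): the DC pedestal carries no feature structure and can never be
chromatic, so including it in the denominator would systematically misbin
DC-heavy chroma detectors as achromatic. Orientation is structure-tensor
anisotropy (threshold 0.4, dominant stripe angle in the image y-up
convention).
"Three-dimensional convolution" is implemented as channel-summed
cross-correlation without kernel flip — visually irrelevant for learned
kernels, but fixed for reproducibility.

## Simulated observers

`observer_model()` states the behavioural world:

* **Ratings** (7-point scale): `rating = round(clip(1 + 6 (offset_a +
  slope_a tau) + bias_o + noise, 1, 7))`, slopes 0.85 / 0.75 / 0.6 for
  translucency / see-throughness / glow. The links share the `tau`
  dependence, so attribute ratings correlate positively (the protocol
  reports only monotone attributes and strong positive inter-attribute
  correlations; the specific slopes are package choices). Observer
  heterogeneity: additive bias (SD 0.35) and a lognormal noise multiplier.
* **Discrimination**: equal-variance Gaussian signal detection with
  per-image realism offsets (SD 0.5). `sdt_calibrate()` inverts the
  marginal error-rate equations in closed form; with targets 28% / 25% the
  implied sensitivity is `d' = 1.41` at criterion `-0.05`. The simulation
  then reproduces those rates within Monte-Carlo error at the full design
  size (300 images x 20 observers x 2 repeats).
* **Forced choice**: softmax over the four standardised endpoint factor
  deltas at temperature 0.4, after multiplying by perceptual salience
  weights (shape 1.6, color 1.0, material 1.2, lighting 0.5). The weights
  encode that observers overwhelmingly report shape when shape and
  lighting change together — without them, a lighting change of equal
  standardised size would split the early-layer vote, which contradicts
  the near-unanimous shape responses the emulated experiment found.
  Deltas are measured on ground-truth factors, not pixels, which is what
  makes end-to-end recovery checks sharp.

## The choice model

`fit_choice_model()` replaces the original Bayesian multilevel multinomial
regression with maximum-likelihood softmax regression on layer
manipulation, pair type and their interaction (reference category
shape/orientation), plus an observer-cluster bootstrap for 95% intervals on
the conditional cell probabilities — the same estimand, desk-scale and
dependency-free. Intervals are t-intervals on the bootstrap standard error
with `df = observers - 1`: in calibration runs, percentile intervals
under-covered noticeably with only 20 clusters (as low as 0.77 for some
cells), while the t-form holds about 0.94 aggregate coverage. Complete
separation (a cell with empty categories) is detected and handled by a
lightly ridge-penalised refit with a warning.

## What a green run does and does not establish

The synthetic world reproduces the *statistical skeleton* of the original
study: class-conditional material structure with nuisance variation in
shape, color and lighting; a latent space whose middle layers alone carry
the material factor; observers whose ratings are monotone in that factor.
Green tests establish that the analysis chain — probing, normalised
distances, tuning curves, editing, ICA, psychophysical summaries — recovers
planted structure correctly and rejects structure that is absent (pixel
baselines, permutation nulls). They do not establish anything about real
photographs, real generators, or real observers: the renderer is not
physical (no subsurface scattering), the generator is affine where a real
one is deeply nonlinear, and the observer model's links and saliences are
stipulated rather than measured. Headline human numbers (the 28%/25% error
rates) enter only as calibration targets for the simulated observer, never
as findings.

## Scales, budgets, and numerical choices

* Default pipeline scale: 150 training stimuli per class and 100 evaluation
  stimuli (the full-scale protocol used 500 and 150) — the largest sizes
  that keep the complete acceptance run within its runtime budget; renders
  at 48–64 px rather than 1024.
* The acceptance coverage criterion is evaluated as aggregate coverage
  (fraction of replicate x cell-probability events covered, target >= 0.90):
  requiring *every* one of 36 probabilities to be covered in >= 90% of runs
  is not attainable at nominal 95% per-interval coverage even for a
  perfectly calibrated procedure.
* Ties, degenerate inputs: zero-variance predictions or ratings yield
  flagged `NA` correlations rather than errors; constant-rating observers
  normalise to 0.5 and are flagged; all-zero choice deltas yield a flagged
  uniform choice.
* Determinism: every stochastic step takes a seed; one master seed fans out
  through `child_seed()` (a fixed LCG-style hash kept below 2^31), so any
  stage can be re-run in isolation bit-identically. The squared-hinge SVM,
  the ICA fixed point, SMACOF and t-SNE all start from seeded states and
  contain no other randomness.
* Latent sets, boundaries and kernel banks serialise to CSV/JSON text
  (no binary container dependency is assumed in the runtime environment).
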