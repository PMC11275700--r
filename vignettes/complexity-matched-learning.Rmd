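---
title: "Layerwise complexity-matched learning: model, evaluation suite, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layerwise complexity-matched learning: model, evaluation suite, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lcml)
```

This vignette is the package's account of the science it implements: the
training scheme and its assumptions, the evaluation statistics, what the
synthetic generators do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## 1. The training scheme

End-to-end training of deep networks leaves intermediate layers weakly
constrained; layerwise self-supervision constrains each stage directly, and
is arguably closer to what biological circuits could implement, since no
gradient information crosses stage boundaries. The premise implemented here
is that layerwise objectives only produce useful hierarchies when each
stage's learning problem is *matched in complexity to that stage's
capacity*. Complexity is operationalized by two knobs per layer:

* **patch size** — how much image content the views contain;
* **spatial deformation strength** — the minimum area fraction of the
  random resized crop that generates the two views.

The default schedule (`default_schedule()`) doubles both between the two
stages — patch 56 → 112 px, views 48 → 96 px, minimum crop scale 0.6 → 0.3 —
mirroring the roughly two-fold growth of receptive field size from cortical
area V1 to V2. The encoder is the canonical first two AlexNet stages with
batch normalization (64 → 192 channels; ReLU and 3×3/2 max pooling as each
stage's two nonlinearities; analytic receptive fields 19 px and 67 px, see
`receptive_field_extent()`).

Each layer's objective operates on view embeddings formed by projecting the
feature map *at every spatial location independently* through a
single-hidden-layer MLP and then global-average-pooling
(`project_and_pool()`). The default loss is the redundancy-reduction
(Barlow Twins) objective on the cross-view feature cross-correlation
matrix: invariance on the diagonal, decorrelation off it. The per-layer
losses are summed for monitoring and early stopping only; gradients are
strictly layer-local. In the layer-2 pass, stage 1 acts as a frozen feature
extractor: no gradient reaches it and its batch-norm running statistics are
not updated. This is a structural property of the implementation (the
backward pass is simply never constructed across the boundary), and the
tests assert it as machine-zero parameter change under a layer-2-only
update.

Alternative objectives for ablation: a sample-contrastive
normalized-temperature cross-entropy over the 2N-view batch
(`sample_contrastive_loss()`, temperature 0.1), and a non-contrastive
negative-cosine objective with an asymmetric predictor and stop-gradient
(`noncontrastive_loss()`). All three have hand-derived analytic gradients,
verified against central finite differences in the test suite — for the
non-contrastive loss against an oracle that respects the stop-gradient
(a full-loss finite difference would see the blocked branch and must *not*
agree, which is also asserted).

### Optimization

Adam with learning rate 0.001 and no weight decay; no learning-rate
schedule (a two-stage model does not benefit from one). Training stops when
the summed validation loss fails to improve by more than a relative
threshold (default `1e-3`) for `stop_patience` (default 5) consecutive
epochs; validation views are regenerated from a fixed seed every epoch so
the validation problem is constant across epochs. Both layers are updated
every batch by default (`mode = "interleaved"`); `mode = "sequential"`
trains layer 1 to its stopping point first, since it is genuinely open
whether the stages should be interleaved or sequenced.

## 2. Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| patch / view size, layer 1 | 56 / 48 | px | complexity knob |
| patch / view size, layer 2 | 112 / 96 | px | ×2 scaling rule |
| crop area scale, layer 1 | (0.6, 0.9) | patch-area fraction | deformation strength 1 |
| crop area scale, layer 2 | (0.3, 0.9) | patch-area fraction | minimum halved |
| aspect-ratio range | (3/4, 4/3) | — | log-uniform; conventional |
| contrast range | (0.8, 1.2) | multiplicative | weak, shared across layers |
| luminance shift | (−0.1, 0.1) | intensity | additive |
| noise sigma | (0, 0.05) | intensity | uniform draw per view |
| λ (off-diagonal weight) | 0.005 | — | conventional setting |
| SimCLR temperature | 0.1 | — | configurable |
| projector dims | 512 hidden / 256 out | — | desk-scale choice |
| Adam lr / weight decay | 0.001 / 0 | — | fixed |
| stop threshold / patience | 1e-3 / 5 | relative / epochs | early stopping |

The exact photometric distortion magnitudes are deliberate "weak
distortion" placeholders, exposed in `augment_spec()` so other values can
be substituted; the same holds for the projector dimensions, λ, and the
temperature. The deformation ladder used in ablations
(`deformation_strength_ladder()`) spans: none, minimum scale 0.6, 0.3,
0.08, and two disjoint-support crops.

## 3. The V1 baseline

`steerable_decompose()` implements a Fourier-domain steerable pyramid:
polar-separable filters with raised-cosine radial profiles (log-frequency
transitions) and `cos^(K−1)` angular tuning, normalized so the squared
filter magnitudes tile the frequency plane — a tight frame, so
analysis–synthesis round trips are exact to machine precision (the test
budget is 1e-4 relative error). Oriented subbands are complex quadrature
pairs obtained by half-plane masking; dyadic downsampling is exact spectrum
cropping, lossless because the recursive lowpass vanishes at and beyond
half-band. Simple cells are the four halfwave-rectified polarity/phase
channels of each subband; complex cells are subband moduli (phase-invariant
within 2% on grating probes, in practice to machine precision for in-band
full-field gratings). `l2_pool()` is the square root of the windowed *mean*
of squares — root-mean rather than root-sum, so constant maps are fixed
points — window 4, stride 2 in subband pixels, valid region only. Defaults
of 4 orientations × 3 scales are a conventional V1 modeling choice and are
configurable for sensitivity checks. Boundary handling is periodic (the
pyramid lives in the DFT domain); no divisive normalization stage is
included.

## 4. Stimuli and simulated neurons

### Texture families and spectrally-matched noise

The texture generator (`make_texture_family()`) is *not* a full
texture-synthesis model. It produces oriented band-pass filtered noise with
a controlled degree of cross-scale phase alignment: a base band at the
family's dominant frequency plus a double-frequency band partially phase-
locked to it (mixing weight = the family's cross-scale correlation
strength), followed by a pointwise contrast nonlinearity. This is the
minimal construction that gives each family graded higher-order,
phase-dependent structure — exactly the property that phase scrambling
destroys, and all the evaluation statistics require is that texture versus
phase-matched noise differ in such structure. Families are distinguished by
orientation, orientation bandwidth, frequency band, cross-scale strength
and contrast exponent; the default 15-family set grades cross-scale
strength from 0.15 to 0.95.

`spectral_match_noise()` replaces Fourier phases with those of a white-noise
field (which guarantees Hermitian symmetry, hence a real image), keeps the
DC component exactly (preserving the mean), and clips to [0, 1] afterwards.
Amplitude preservation is exact *before* clipping and is asserted at 1e-6;
the clipped fraction is recorded and generation is rejected if it exceeds
5%, so clipping cannot silently distort the spectrum. Grayscale is the
default channel mode — the modulation statistics of interest are
luminance-defined — with RGB handled per channel with shared phases.

The training corpus generator (`make_training_corpus()`) produces 1/f-
amplitude noise backgrounds with a few localized oriented band-limited
elements: the coarse spectral statistics of natural images (radially
averaged power slope near −2 on log–log axes, asserted within [−2.5, −1.5])
plus some oriented structure for the objectives to latch onto. What it does
*not* emulate: occlusion, scale-space structure of scenes, photometric
nonstationarity, semantic content. Consequently, passing tests show the
training machinery optimizes its objectives and orders complexity
correctly on this distribution — they do not show that features learned
here match those learned on natural images.

### Simulated V2 neurons

`simulate_v2_neurons()` has two modes, each built to make one part of the
evaluation suite checkable against ground truth:

* **metadata mode** — `response = baseline + gain · 1[texture] ·
  m[neuron, family] + noise`, rectified at zero. The noise-free modulation
  index is analytic, `Rmod = g/(2b + g)` with `g = gain · m`, so
  `modulation_index()` can be verified exactly and its convergence measured
  (within 0.02 at 100 samples/family and noise at 1% of baseline).
  Defaults (baseline U(5, 15) spikes/s, gain U(2, 10), graded family
  strengths) put the population median Rmod near 0.1 with family averages
  spanning ≈ 0.04–0.16, a physiologically plausible range.
* **feature mode** — `response = softplus(3 + w·features) + noise` with
  stored weights, for PLS parameter-recovery tests. The +3 offset keeps
  neurons in the near-linear regime of the softplus so that a linear
  readout can recover them in the noise-free limit; recovery tests use a
  generating basis of dimension 20, inside the span of the default
  25-component regression.

These simulations reproduce the *shape and metadata* of the classic
103-neuron V2 texture dataset (103 × 450 with 15 × 15 × 2 design), not its
biology: passing recovery tests validates the estimators, not any claim
about real V2.

## 5. The predictivity protocol

`fit_pls_predictivity()` fits partial-least-squares regression (SIMPLS,
implemented in the package and cross-checked against an independent
implementation in the regimes where PLS algorithm families provably
coincide: single-response vs NIPALS, full-rank vs OLS) from features to all
neurons jointly, per cross-validation fold (default 10), scoring each
neuron on held-out images by squared Pearson correlation. 25 components by
default, capped at the fold training size and the feature count, and
stopped early once the deflated cross-covariance is numerically exhausted —
components beyond the effective rank only amplify round-off (this also
makes scores exactly invariant to duplicated feature columns). Degenerate
(constant) predictions or observations score 0 and are flagged. No
noise-ceiling normalization is applied: simulated data has no repeat
structure to estimate a ceiling from; a ceiling hook would slot in where
per-neuron scores are aggregated.

Layer selection follows the validation protocol: `select_best_layer()`
picks the layer with the best *validation* median, ties to the lower layer,
and the reported score must come from an untouched test split.
`partition_neurons()` sorts neurons by baseline-model score and takes
ceiling(N/4) top (V1-like) and bottom (V2-like) quartiles — 26 of 103 —
with boundary ties resolved by stable sort order. Distributional comparison
uses matched-probability empirical quantiles (`qq_compare()`); family-rank
comparison uses Spearman correlation with the significance of a difference
of two correlations assessed by paired bootstrap over neurons (default
10,000 resamples, family means recomputed per resample, two-sided, shared
reference resample across the pair) — a pragmatic stand-in where no
canonical test exists.

## 6. Numerical choices

* **Interpolation**: bilinear with half-pixel-centre (align-corners=false)
  semantics, implemented in the package so view generation is
  bit-reproducible across platforms.
* **Random resized crop**: the area fraction is drawn uniformly from its
  range and the aspect ratio log-uniformly from its *feasible* sub-interval
  given that area. The conventional rejection-sampling implementation
  biases realized areas downward (large-area, extreme-aspect proposals get
  rejected); conditioning the aspect draw keeps the stated area law exact.
  Infeasible geometry falls back to the maximal centred crop, flagged.
* **Centering in the cross-correlation**: the default implements the plain
  normalized cross-moment; `center = TRUE` subtracts per-feature batch
  means first (the original redundancy-reduction convention). Both paths
  are tested; whether embeddings should additionally be batch-normalized
  before the loss is left to the caller, since the normalization by
  per-feature norms is already part of the correlation definition.
* **Batch norm**: per-channel statistics over batch × space; training mode
  uses batch statistics and updates running moments (momentum 0.1);
  inference uses running moments, making `extract_features()`
  deterministic. The frozen stage-1 pass in layer-2 training uses batch
  statistics without updating the running moments.
* **Degenerate inputs**: zero-norm feature columns are rejected with a
  named-feature diagnostic; `Rmod` entries with `tex + noise = 0` become
  `NA`, are excluded pairwise from averages and counted; non-finite losses
  abort training with a diagnostic; convolution/pooling geometry that
  collapses to zero extent is rejected.
* **Seeding**: every generator routes randomness through a
  seed-save/restore wrapper, and composite generators derive per-item
  seeds, so outputs are bit-reproducible and insensitive to surrounding
  RNG use. Ablation-grid cells derive independent seeds from the cell
  definition and cache checkpoints, so grids are resumable and idempotent.

## 7. Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the full pipeline at
deliberately modest sizes: the canonical 450-image stimulus design at
64 px; 103 simulated neurons; V1 feature matrices of ≈ 25k dimensions; and
a training corpus of 200 images at 128 px for 20 epochs (about 4 minutes on
one CPU), which is ample to demonstrate loss reduction, determinism and
gradient isolation. These sizes are the package's chosen study conditions
for a desk-scale, fully-reproducible demonstration; nothing in the
implementation is specific to them.

## 8. Known limitations

* Two stages only; extending the complexity-matching rule deeper needs
  larger images and a principled capacity measure for later stages.
* The texture generator produces one class of higher-order structure
  (cross-scale phase alignment); real texture families span a much richer
  statistics space.
* Metadata-mode neurons are label-driven, so image-computable models
  (including the V1 baseline) explain them poorly by construction — they
  validate the statistics, not model comparisons.
* No noise-ceiling correction, no divisive normalization in the V1
  baseline, no color modeling.
* Pure-R training is practical at desk scale but not at natural-image
  dataset scale.
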