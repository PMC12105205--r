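---
title: "Automated fetal-head segmentation, biometry and growth classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated fetal-head segmentation, biometry and growth classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalbiom)
```

## The problem

Fetal head circumference (HC) and biparietal diameter (BPD) are the two
standard biometric measurements taken from a transthalamic ultrasound plane.
Compared against gestational-age (GA) reference ranges, they flag
microcephaly (head more than 2 SD below the GA mean) and macrocephaly (more
than 2 SD above). Measuring them by hand is slow and operator-dependent;
`fetalbiom` implements the full automated chain — segment the skull from the
image, fit an ellipse to the predicted mask, convert its geometry to
millimetres, and apply the z-score rule — together with a synthetic phantom
generator that makes every stage testable against analytic ground truth.

## The phantom generator: what it emulates, and what it does not

Real training data for this problem is a clinical ultrasound still with an
expert-traced head contour. The generator replaces it with a *phantom*: a
bright elliptical skull rim on a dark speckled background, a mid-intensity
interior, and an exact filled-ellipse mask.

A phantom is sampled in measurement space first. Given a reference table and
a GA, an HC z-score is drawn from a standard normal truncated to the
requested class band (`force_micro`: z < −2, `force_macro`: z > +2,
`force_normal`: |z| ≤ 2; `random` draws are clipped to |z| ≤ 3.5 so every
head stays renderable). The HC in mm follows as mean + z·SD. The ellipse
axes come from a fixed *cephalic index* (minor/major semi-axis ratio),
0.78 by default — a mid-range value for fetal heads; it is configurable
because head eccentricity varies. At fixed ratio the Ramanujan perimeter is
exactly linear in the semi-major axis, so the inversion HC → (a, b) is
closed-form rather than iterative. BPD is defined outer-to-outer as the full
minor axis, consistent with the rendered mask boundary; a scale factor is
available for outer-to-inner caliper conventions.

Pixel spacing is drawn per image so the semi-major axis spans a realistic
32–50 px of the 128×192 frame, clamped to (0.05, 1] mm/px — mimicking the
varying zoom/depth of real scans. Speckle is a multiplicative mean-one gamma
field (shape 3, so variance 1/3), Gaussian-smoothed (σ = 1 px) to give it
lateral correlation, mixed at weight 0.7. These defaults produce clearly
textured but learnable images; weight 0 gives the noiseless limit used by
the biometry oracle tests. Optional angular shadow sectors emulate bone
shadowing and are off by default.

What passing tests on phantoms shows: that the architecture can be trained
to high overlap by the stated protocol, that the measurement pathway is
geometrically accurate, and that the classification rule is exact. What it
does not show: robustness to real speckle statistics, probe artefacts,
adjacent anatomy, truncated or irregular skulls, or annotation noise — the
phantom skull is a perfect ellipse, which is precisely why biometry recovery
can be held to 1–2%.

## The reference table

The GA reference table (mean/SD of HC and BPD per week) is an *input*. The
packaged default is synthetic and illustrative, **not clinical**: HC means
rise linearly from 98 mm at week 14 to ≈296 mm at week 40 with SD = 3% of
the mean, and the BPD columns are derived from the HC columns through the
0.78 cephalic index so that HC and BPD z-scores agree on phantom heads. The
values are deliberately chosen so that every head with |z| ≤ 3.5 fits the
frame within the admissible spacing range. Substitute a published growth
standard (WHO, INTERGROWTH-21st) via `read_reference_table()` for any use
beyond synthetic experiments.

## The segmenter

The model is an optimized SegNet encoder–decoder. Five encoder blocks of
[3×3 conv → batch-norm → ReLU] repeated 2/2/3/3/3 times, each followed by
2×2 max-pooling, take a 128×192×3 input down to a 4×6×512 bottleneck
(channels 64/128/256/512/512 at width multiplier 1). The decoder mirrors
the encoder; each block up-samples by 2 and then applies its convolutions,
with the channel reduction assigned to the first convolution of the block —
the only reading under which the published dimension plan is internally
consistent, since resizing cannot change channel counts. A 1×1 convolution
maps to K logit channels (K = 1 binary), and a sigmoid is applied at
evaluation time; `predict_mask()` thresholds at 0.5 with `>=` semantics
(an exactly-0.5 probability is foreground).

Two up-sampling modes are provided because the architecture admits both
readings: smooth bilinear interpolation (the default, matching the
"simplified decoder" refinement) and classic max-unpooling driven by the
stored pooling indices (`upsample_mode = "unpool_indices"`). Both are
exercised by the test-suite; which one a given published accuracy figure
used is not determinable, so neither is privileged beyond the default.
In unpooling mode, because the channel reduction sits in the first
convolution *after* up-sampling, the decoder can carry a multiple of the
encoder's channel count at an unpool point; the stored pooling switches
are then shared across channel groups.

Batch-norm follows every convolution (the mathematical description defines
it even though the layer table omits it), with ε = 1e-5 and running
statistics updated with momentum 0.1. On very short runs (a couple of dozen
mini-batches) the running statistics still lag the batch statistics and
evaluation-mode predictions are poor — this is inherent to the momentum
scheme, converges within roughly one epoch at cohort scale (36 batches per
epoch), and is why the tiny smoke tests assert artifact contracts rather
than accuracy. Weights are He-normal initialized; 3×3 convolutions use
padding 1 so every block preserves spatial dimensions, as the dimension
plan requires. Optional dropout after encoder blocks 4–5 is available but
off by default (no rate or placement is prescribed anywhere, so it is
exposed as a switch rather than silently enabled).

The whole network — convolution via nine strided GEMM accumulations per 3×3
kernel, pooling, unpooling, bilinear resampling, fused batch-norm+ReLU, and
their exact adjoints for backpropagation — is implemented in C++ on the CPU
with float32 arithmetic. Backpropagation is verified two ways: adjoint
identities for every linear operator, and a directional finite-difference
check of the full network gradient (ratio within 2% of 1 at h = 1e-6).

## Training protocol

The loss is the hybrid `alpha * BCE + (1 - alpha) * DiceLoss` with
α = 0.5. BCE is mean-per-pixel with probabilities clipped to
[1e-7, 1−1e-7]; the soft Dice loss uses Σpy overlap with smoothing s = 1 in
numerator and denominator (s is not prescribed; 1 is the common choice and
guards empty masks). Mean rather than sum reduction is used so loss values
are batch-size-invariant; consequently loss *magnitudes* are not comparable
with sum-reduction runs, only trends.

Optimization is Adam at lr 0.001, mini-batches of 8 (batch size is not
prescribed; 8 fits comfortably in CPU memory), weight update per mini-batch,
an 80/20 stratified split, and ReduceLROnPlateau on the validation loss
with mode min, factor 0.5, patience 20, relative threshold 1e-4, cooldown
0, min_lr 0, eps 1e-8. The reduction fires when the count of consecutive
non-improving epochs *reaches* patience, so a 21-epoch plateau (one
improving epoch followed by 20 flat ones) produces exactly one halving —
the semantics under which the protocol's worked example is consistent.
Checkpointing keeps the weights with the best validation loss. A sanity
check (one forward/backward pass: finite loss, nonzero gradients) runs
before the first epoch, and training aborts with diagnostics on a
non-finite loss. Early stopping is implicit in the scheduler; an optional
hard stop after a configurable number of non-improving epochs is off by
default. Train-time augmentation applies independent horizontal and
vertical flips with probability 0.5 to image and mask jointly; evaluation
applies resize and normalization only.

Per-epoch history records train/validation loss, thresholded Dice, and soft
Dice (both are logged because either could be meant by a per-batch "Dice
coefficient" in a training log), plus the learning rate.

## Biometry

Measurement from a predicted mask proceeds: fill enclosed holes → keep the
largest 8-connected component (ties broken by scan order and flagged) →
trace the outer contour → scale contour coordinates to millimetres
(anisotropic per-axis spacing supported) → direct least-squares ellipse fit
(Fitzgibbon, with the Halir–Flusser partitioning and data centering for
conditioning) → HC = Ramanujan perimeter of the fitted ellipse,
BPD = full minor axis.

HC is the *fitted-ellipse* perimeter, not the raw contour arc length: the
discrete contour of a noisy mask systematically overestimates perimeter,
and the ellipse-caliper convention matches clinical practice. The raw
polygonal arc length is still emitted as a diagnostic column. Because mask
pixels are defined by "center inside the curve", the centers of boundary
pixels sit on average half a pixel inside the continuous outline; a fixed
+0.5 px outer correction per semi-axis restores the outer-to-outer
convention. This correction is geometric, not tuned: with it, noiseless
phantom recovery achieves median relative HC and BPD errors below 1% with a
95th percentile below 2% across 200 random phantoms.

Coordinates follow x = column, y = row, 0-based pixel centers; rotation is
measured from the x-axis in degrees within [0, 180).

## Classification

`classify_case()` computes z = (HC − mean(GA)) / SD(GA), interpolating mean
and SD linearly between integer weeks, and applies the strict rule:
microcephaly iff z < −2, macrocephaly iff z > +2, otherwise normal. Both
published phrasings of the macrocephaly cut-off (98th percentile ≈ +2.05 SD
vs +2 SD) are close; +2 SD is the default and the threshold is a parameter.
A z of exactly ±2 is normal ("more than 2 SD" read strictly). The quoted
one-SD phrasing of microcephaly in one operational definition is read as
the ±2 SD rule stated in full elsewhere. Classification is HC-primary; the
BPD z-score is reported for context, and a strict concordance mode (both
measurements must agree before an abnormal label stands) is available but
off by default. Labels are exactly reproducible: reclassifying the stored
`hc_true` of generated phantoms recovers the stored label for 100% of a
1000-phantom cohort, because generation and classification share one rule.

## Problem sizes and numerical choices

The scaled-down acceptance experiment generates 360 phantoms, splits 80/20,
and trains the width-0.25 network (channels 16/32/64/128/128) for 8
epochs — the phantom task converges well inside the 60-epoch cap, with
validation Dice typically crossing 0.97 around epoch 3–6 — then scores the
best checkpoint on the 72 held-out images. Width multipliers below 1 scale
every channel count by rounding (minimum 1) and leave the spatial plan
untouched.

Other fixed numerical choices: mask binarization threshold for 8-bit PNGs
is >127; Dice of two empty masks is 1 (perfect-agreement convention);
degenerate metric denominators yield 0 plus a flag rather than an error so
batch evaluation stays total; the 80/20 split uses largest-remainder
rounding within label strata so the overall train count is exact; and all
randomness descends from a single user seed fanned out to named substreams
(cohort, per-image spec, speckle, split, initialization, shuffling), with
the caller's RNG state always restored.

## Known limitations

Phantoms are single perfect ellipses: no skull gaps, no neighboring
anatomy, no acoustic artefacts beyond multiplicative speckle and optional
wedge shadows. The default reference table is synthetic; clinical use
requires a published standard. The segmenter is CPU-bound and sized for
desk-scale cohorts, not for 700-image clinical training runs at width 1.0.
The pipeline takes GA as an input — it does not estimate GA from biometry.
None of this is a diagnostic tool; it identifies biometric deviations on
synthetic data and does not replace clinical assessment.
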