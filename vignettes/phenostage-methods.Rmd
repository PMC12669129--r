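---
title: "Growth staging from top-view multi-plant images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth staging from top-view multi-plant images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

`phenostage` implements an instance-level, phenotype-based growth staging
pipeline for rosette crops such as sweet basil grown in fixed multi-pot
beds and photographed from above. The developmental trait it stages on is
the number of leaf pairs visible at the shoot apex: basil has opposite
(decussate) phyllotaxy, so leaves emerge in pairs, each pair rotated
roughly 90 degrees against the previous one, and the apex remains visible
from above even when the canopy closes. Counting pairs at the apex is
therefore robust to the lighting casts, overlap and perspective effects
that defeat biomass- or leaf-area-based staging, and it maps directly
onto BBCH-style discrete stage codes.

The pipeline has four stages, mirroring its module layout:

1. **Detection** (`reference_detect()`, or any detector honouring the
   box contract): one axis-aligned box with a confidence per plant.
2. **Box post-processing and ordering** (`postprocess_boxes()`):
   confidence filtering (strictly above 0.706 by default), nested-box
   removal with a 10-pixel tolerance, an exact-count gate (8 plants),
   and row ordering -- one-dimensional K-means on the vertical box
   centers into 3 rows, rows top to bottom, plants left to right within
   a row. The resulting reading order is what makes the per-pot label
   assignment stable across frames.
3. **Leaf-pair regression** (`train_regressor()` / `predict()`): a small
   convolutional network regresses a continuous pair count from each
   cropped instance, trained with the Huber loss and AdamW.
4. **Staging** (`round_clamp()`, `map_stage()`): half-up rounding,
   clamping, and interval mapping to Level 1 (<= 2 pairs), Level 2 (3-4)
   or Level 3 (>= 5).

A regression head rather than a classifier is used for the counting step
because it penalises errors by magnitude: predicting 5 when the truth is
2 is worse than predicting 3, and the loss should say so.

## Counting under leaf loss

Plants with abscised or removed leaves are *not* discarded. The label is
the effective pair count computed by `effective_pairs()`: a pair with a
single missing leaf still counts (the node exists and its stage
interpretation is unchanged), while a pair with both leaves gone reduces
the count by one. Frames that cannot be labelled reliably at all are
excluded by `exclude_frames()`: multiple seedlings in one pot, dark
(lights-off) frames detected photometrically by a mean-luminance cap,
plants more than half out of frame or with an invisible apex, and beds
with fewer than the expected number of germinated plants.

## The synthetic scene generator

No real chamber imagery ships with the package, so every claim its tests
make is grounded in the procedural generator (`random_scene()`,
`make_corpus()`), which emulates the acquisition geometry and the known
failure modes of fixed-camera bed imaging:

- a 3-2-3 pot grid around a central humidifier disk (eight pots
  "around" a central obstruction is the only arrangement consistent with
  three clusterable rows; the layout is configurable);
- decussate rosettes: elliptical leaves in opposite pairs, successive
  pairs rotated ~90 degrees with a small fixed spiral deviation, sizes
  strictly decreasing toward the apex so the apex disk is never covered;
  juvenile tiers are rendered a lighter green than older ones, as in
  real basil, which is what makes the tier count legible in a resized
  crop;
- per-scene multiplicative RGB casts emulating LED lighting (the
  reference detector normalises these away before thresholding),
  additive Gaussian pixel noise, and uniform anchor jitter;
- the five anomaly classes: multi-seedling pots, dark frames (scaled to
  a mean luminance below 8/255), plants pushed out of frame, empty pots,
  and leaf-removed plants (kept, with adjusted labels).

Anomalies are injected by deterministic assignment -- the first
`floor(rate * n)` scenes of a seeded shuffle per category -- so a corpus
composition is exactly reproducible, not merely so in expectation.
Everything downstream of a seed is bit-deterministic, including the
rendered PNG bytes.

The canvas defaults to 820 x 616 px, a quarter-scale of the 3280 x 2464
chamber resolution with the aspect ratio preserved; it keeps a full
rendered corpus affordable on one CPU while leaving the smallest leaves
several pixels wide.

What the generator does **not** emulate: perspective distortion, leaf
droop and self-occlusion in 3D, soil texture, specular highlights, and
continuous growth between frames. Tests passing on synthetic corpora
therefore validate the pipeline's logic, determinism and its ability to
recover known parameters -- they do not certify real-chamber accuracy,
for which the detector and regressor would be retrained on annotated
imagery behind the same contracts.

## The reference detector

The bundled detector is deliberately classical: per-channel
normalisation by the 99th percentile (cancelling multiplicative casts),
a green-dominance threshold, morphological closing, connected
components, and a tight box per component with confidence
`min(1, area / reference_area)`. Its default `reference_area` (350 px)
is the footprint of the smallest genuine rosette the generator produces,
so real plants saturate at confidence 1 and survive the 0.706 threshold,
while noise blobs score low. A learned detector can replace it anywhere:
the pipeline consumes only the box table (`pipeline_config(detector =
<function>)`, or a detections CSV via `read_detections()`), and a
ground-truth replay detector isolates downstream components from
detection error in tests.

## Regressor, loss and training

The default backbone (`small_conv`) is a stack of three 3x3
convolution / LeakyReLU / 2x2 average-pool blocks (8, 16, 32 channels)
over a 48 px input, global average pooling, head-only dropout and a
single linear output unit; `residual_small` adds a second convolution
with an identity skip per block. The engine is written on base R matrix
algebra (im2col + GEMM through BLAS) with analytically derived gradients
that the test suite checks against finite differences. A pretrained
18-layer residual backbone is intentionally not shipped: it would
require downloaded weights, and nothing in the desk-scale task needs it.

The Huber loss drives training: `e^2/2` for residuals below `delta`,
`delta * (|e| - delta/2)` beyond, continuous with matching slope at the
knee. Pair labels are integer counts whose annotation is mildly noisy
(leaf emergence is gradual), so a loss that is quadratic near zero but
linear in the tails resists occasional off-by-one labels. `delta`
defaults to 1 -- the natural unit here is one leaf pair -- and is
exposed in `regressor_config()`.

`regressor_config()` carries the tuned full-scale defaults: learning
rate 3.67e-5, AdamW weight decay 4.81e-4, dropout 13.4% (head only),
LeakyReLU, early-stopping patience 7, no learning-rate scheduler.
`synthetic_train_config()` overrides the learning rate to 3e-3 and caps
training at 60 epochs for the desk-scale synthetic corpora this package
trains on: at 3.67e-5 the small corpus converges far too slowly to be
useful, while 3e-3 converges stably in a few minutes. Inputs are
standardised per channel with training-set statistics stored in the
fitted model. The head bias starts at the training-label mean so the
optimiser spends no epochs discovering the scale. Training is
deterministic given `cfg$seed` (initialisation, shuffling, dropout and
augmentation all derive from it).

Augmentation (`augment_config()`) uses colour jitter of +-10.6%
brightness, +-24.5% contrast, +-36.6% saturation and +-5.6% hue,
horizontal flips with probability 26.3%, and rotations up to +-10
degrees -- all label-preserving by construction (no transform can change
a pair count), which the suite asserts. The parameter-recovery
experiments train *without* augmentation: the generator already
randomises lighting per scene, and photometric/rotational jitter mainly
simulates real-chamber variation the synthetic test crops do not
exhibit, so augmented training measurably mismatches the clean held-out
distribution at this scale.

`search_hyperparams()` provides a seeded random-search harness with
median pruning (a trial clearly worse than the median of previous trials
at the pruning epoch is aborted); it is an optional tool, not part of
the tested defaults.

## Evaluation

Detection is scored by greedy one-to-one matching in decreasing
confidence order at an IoU threshold; the matching rule is the standard
detection-evaluation convention (the one degree of freedom the upstream
method leaves open). Precision is defined as 1 with no predictions,
which threshold sweeps need. `f1_confidence_curve()` sweeps observed
confidences and breaks F1 ties toward the highest threshold;
`average_precision()` uses all-point interpolated precision-recall
integration, with mAP@0.5:0.95 averaging IoU 0.50-0.95 in steps of 0.05.

Counting is scored by MAE/MSE/RMSE/R^2 (R^2 raises on zero-variance
targets rather than returning NaN), staging by accuracy, support-weighted
F1 and a row-normalised confusion matrix. `kfold_cv()` runs a seeded
instance-level k-fold partition (fold sizes within one of each other)
with an inner validation split for early stopping.

## Numerical choices and conventions

- Box coordinates are continuous pixels, origin top-left, y down;
  cropping uses half-open integer ranges, so box `(0, 0, 10, 10)` is
  exactly a 10 x 10 pixel crop.
- Confidence filtering is strict (`conf > threshold`).
- Nested-box removal processes boxes largest-area first (ties by higher
  confidence), removing a box only if a kept, at-least-as-large box
  contains it within the tolerance; this makes the operation idempotent.
- Filtering precedes nesting removal in the default chain; the two do
  not commute and the suite pins the order.
- Row clustering runs K-means on `cy` only, with deterministic quantile
  initialisation, so the one-dimensional solution is seed-stable;
  within-row sorting breaks `cx` ties by `cy`, then input position. An
  empty cluster marks the frame `degenerate_rows` rather than guessing.
- Rounding is half-up (2.5 -> 3), clamped to `[0, max_pairs]`.
- The train/val/test split is floor-floor-remainder: with 12,871 samples
  at 70:20:10 this gives exactly 9,009 / 2,574 / 1,288.
- Dataset splits are instance-level by default, matching how the
  upstream crops were split; note that crops of the same plant from
  consecutive frames can then land in different splits, which flatters
  test metrics -- a scene-grouped split is the obvious remedy when that
  bias matters.

## Problem sizes used by the tests and the acceptance script

The parameter-recovery experiment renders 190 scenes (1,520 crops after
exclusions), splits 70:20:10, and trains `small_conv` for at most 60
epochs at 48 px, the patience-7 early stop governing the actual
length -- several minutes on one CPU; the bar is held-out MAE <= 0.25
and three-level stage accuracy >= 0.95. Detector acceptance
uses a fresh 100-scene clean corpus (800 plants) at IoU 0.5. The
ordering property is exercised on 1,000 jittered 3-2-3 layouts with a
jitter band of 40% of the inter-row spacing (beyond roughly half the row
gap, row membership stops being decodable from vertical position alone,
for any method). Unit tests use smaller renders and a greenness-based
linear stand-in trainer where only mechanics, not learning capacity, are
under test.

## Known limitations

- The synthetic-to-real gap: see the generator section; real deployments
  must retrain both learned components on chamber imagery.
- K-means row ordering assumes a known, fixed row count and rows
  separable by vertical position; it does not infer layouts.
- Frames failing the exact-count gate are skipped, never retried at a
  lower threshold; at inference time this trades coverage for label
  integrity, and the skip log quantifies the cost.
- The CNN engine is CPU-only and sized for desk-scale corpora; it is not
  a general deep-learning framework.
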