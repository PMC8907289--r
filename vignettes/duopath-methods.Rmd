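---
title: "Methods: asymmetric dual-path 3-D CNNs for MR-based tumor grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric dual-path 3-D CNNs for MR-based tumor grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

WHO Grade I and Grade II meningiomas call for different management, but
grade is established histologically, after surgery. This package implements
a radiological classifier that predicts grade from two routinely acquired,
co-registered preoperative MR sequences: T1 contrast-enhanced (T1-CE),
where the tumor enhances, and T2-FLAIR, where peritumoral edema is
hyperintense.

The model is a 3-D CNN with **two encoding paths**, one per sequence. Each
path stacks `levels` blocks of: 3×3×3 convolution → ReLU → dropout (0.3) →
3×3×3 convolution → ReLU → 2×2×2 max-pooling, with the filter count
doubling after each pooling. The paths are **asymmetric**: the default
first-level allocation is 18 filters for T1-CE against 2 for T2-FLAIR
(giving 18→36→72 vs 2→4→8 at depth 3), against a symmetric 10:10 reference
with the same first-level total of 20. The rationale is that T1-CE carries
most of the grade signal while FLAIR contributes a weaker, complementary
cue; the unequal budget biases capacity accordingly without discarding the
second channel. After the encoders, each path's final feature block is
flattened; the two vectors are concatenated and passed through three fully
connected layers (defaults 256, 64, 2) with dropout 0.3 after the first
two, ending in a softmax over {Grade I, Grade II}. Single-path variants
(T1-CE only, FLAIR only, or both channels stacked into one encoder) serve
as baselines.

Training is Adam on cross-entropy. Weights are initialized
Glorot-normally: a truncated normal centred at zero with nominal SD
`sqrt(2/(fan_in + fan_out))`, where convolution fans are channel counts ×
kernel volume (27).

## Choices the architecture description leaves open

The source description of this architecture is schematic in places; the
following were design decisions, all exposed in `net_config()`:

* **Encoder depth 3** (default): keeps a 64³ input at an 8³ bottleneck and
  preserves the 18:2-vs-10:10 comparison; the depth is configurable and
  the smoke/benchmark profiles in the tests use 2 levels on small ROIs.
* **Fusion = flatten + concatenate** of the two paths' final feature
  blocks — the minimal layer-level fusion consistent with feeding "both
  paths" into shared fully connected layers.
* **Same-padding convolutions**: only pooling reduces spatial extent, so
  the extent halves exactly per level and `input_shape` must be divisible
  by `2^levels`.
* **Fully connected widths (256, 64, 2)**: unstated upstream; chosen small
  enough for desk-scale training. The layer sequence is
  dense → dropout → dense → dropout → dense → softmax, with no
  nonlinearity between the dense layers (the minimal reading of the
  description; the encoder ReLUs provide the nonlinearity).
* **Truncation at ±2 nominal SDs** for the initializer, the common
  convention. Truncation shrinks the realized SD by the factor
  `sqrt(1 − 2·a·φ(a)/(2Φ(a)−1)) ≈ 0.8796` at `a = 2`; the tests assert the
  empirical SD against `glorot_std() × 0.8796`, i.e. the *nominal* SD is
  the distribution parameter, not the realized moment.
* **Single-path filter budget**: the single-path baselines get a
  first-level count of 20 — the sum of the dual paths — so all five
  variants have equal first-level capacity (config-exposed as
  `single_path_filters`).

## Preprocessing

Volumes are exchanged as NIfTI-1 (the package carries its own minimal
reader/writer: 3-D payloads, sform/qform affines, uint8 masks, float32
images, gzip). Rigid cross-sequence registration is assumed done upstream;
the package only resamples grids:

* `resample_to_reference()` — pulls the moving volume onto the reference
  grid through world space (trilinear for images, nearest for masks, zero
  fill outside the field of view);
* `resample_isotropic()` — a 1 mm isotropic grid preserving world extent;
* `crop_to_roi()` — a fixed-shape window centred on the mask centroid.
  Convention: 0-based voxel indices, half-open windows
  `[origin, origin + shape)`, `origin = centroid − (shape−1)/2` rounded
  with ties toward the lower index. Channels share one window, so
  cross-channel alignment is preserved exactly. Inputs are **not**
  multiplied by the mask by default (tumor context is retained; a
  `masked` flag exposes the alternative), because the upstream description
  contours tumors but never states that background is zeroed.
* `normalize_intensity()` — z-score over the support (foreground mask, or
  nonzero voxels), constants mapping to zero.

Tumor volumetry is voxel counting: `mask_volume_mm3()` is foreground count
× voxel volume, and `compute_r_ratio()` forms `R = V_T1CE / V_T2FLAIR`.

## Cross-validation protocol

`make_folds()` permutes subjects by seed and partitions them into `k`
near-equal test blocks, so **every subject is tested exactly once**; per
fold, a validation set (default `ceiling(n/k)`, i.e. 10 of 96) is drawn
from the non-test remainder and the rest train. The reference protocol
states uniform 10/10/76 splits over ten folds, which implies 100 test
slots for 96 subjects; since the published confusion tables aggregate
exactly 96 predictions, each subject must have been tested once, and the
near-equal partition (test blocks 10×6 and 9×4) is the reconciliation this
package adopts. Training uses random in-plane rotation augmentation
(uniform in ±15° about the axial plane by default, applied identically to
both channels, trilinear with zero fill), monitors validation loss every
epoch, and returns the model at the best validation epoch. All
stochasticity — initialization, shuffling, dropout, augmentation, fold
assignment — flows through R's seeded RNG, and the compiled kernels are
deterministic, so a fixed seed reproduces a run exactly.

The reference learning rate is 2×10⁻⁵ with 1000 epochs; `train_config()`
defaults to desk scale (50 epochs) and warns when the learning rate leaves
the tested range [10⁻⁶, 10⁻⁴]. Batch size (unstated upstream) defaults
to 4. The decision threshold for confusion counts is 0.5 on the Grade-II
probability, ties predicted positive (documented, deterministic).

## Evaluation

Grade II is the positive class everywhere: sensitivity is the fraction of
Grade II called II, specificity the fraction of Grade I called I. Metrics
with zero denominators are flagged `NA`, never reported as 0. The ROC is a
threshold sweep over the unique predicted probabilities and the AUC its
trapezoidal integral, which equals the Mann–Whitney rank statistic with
ties counted ½ — the test suite asserts this equivalence to 1e-12 against
a brute-force pairwise oracle. The headline AUC pools out-of-fold
probabilities (the only way a single curve covers all subjects); per-fold
metric ranges are reported as min–max, and pooled values need not nest
inside them. Stratified accuracy (by tumor location) uses
linear-interpolation quantiles for the cohort R summary (IQR = Q3 − Q1,
R's default type-7 quantile).

## The phantom: what it emulates, and what it does not

`generate_subject()` builds a two-channel subject on an isotropic grid:

1. **Channel 1 (T1-CE-like):** a randomly placed ellipsoid (mean radius
   uniform in `tumor_radius_range_mm`, mild random anisotropy) with
   boundary perturbation from a low-frequency directional field (a small
   base amplitude of 0.05 for both classes, plus `grade2_spiculation`,
   default 0.25, for Grade II), and intratumoral Gaussian texture with
   class-specific SD (`grade1_heterogeneity` 0.10 vs
   `grade2_heterogeneity` 0.30 around a contrast-enhancement plateau
   of 1.0).
2. **Channel 2 (FLAIR-like):** the halo. A ratio `r` is drawn from a
   normal(0.83, 0.50) truncated by rejection to [0.07, 3.19] —
   the clinical R distribution — **independently of grade**, and the
   FLAIR mask is the set of voxels with smallest ellipsoid-metric radius
   whose count is `V_T1CE / r`. Growing/shrinking in the ellipsoid metric
   makes the mask-derived R exact up to rounding, guarantees the nesting
   invariant (core ⊆ halo iff r ≤ 1), and replaces a morphological
   dilation-with-bisection by an order-statistic that hits the target
   count directly. Intensity is a 0.8 plateau with fixed texture, plus a
   weak Grade-II-only radial ramp scaled by `flair_signal_weight`
   (default 0.05) — deliberately nonzero so that the optimal fusion
   weighting is asymmetric but not T1-only.
3. **Noise:** additive Gaussian (`noise_sd` 0.05) on both channels, after
   the masks are derived. Rician noise, bias fields, scanner variation and
   any anatomical background are *not* modeled; location labels are
   cosmetic metadata used only to exercise stratified evaluation.

Class balance defaults to the clinical 55:41 and locations to 43:20:18:13:2.
If a drawn tumor (plus its worst-case halo reach) cannot fit strictly
inside the grid, the radius is shrunk and placement retried a bounded
number of times before erroring.

Because the effect sizes distinguishing the grades are free parameters
(no quantitative imaging biomarker is published — the clinical network
learned its discriminant implicitly), a green benchmark establishes that
the pipeline can recover a *planted* channel-1-dominant signal under the
clinical R confound, not that it would reach any particular accuracy on
real patients. The planted signal at defaults is strong: a logistic model
on two handcrafted features (intratumoral SD, boundary surface-to-volume
ratio) separates the classes almost perfectly, which is intentional — it
makes the training-based tests sharp at desk scale.

Note on the R moments: `r_mean`/`r_sd` parameterize the *untruncated*
normal. Truncation to [0.07, 3.19] shifts the true mean to ≈0.898 and SD
to ≈0.441; both remain within the acceptance tolerances (±0.08, ±0.10) of
the configured values, which therefore absorb truncation shift plus
sampling noise.

## Numerical and engineering notes

* Convolutions run as compiled im2col + GEMM (RcppArmadillo); activations
  are `channels × (voxels·batch)` matrices with x-fastest voxel order. The
  backward pass is checked against central finite differences to 1e-5.
* 2×2×2 max-pooling stores argmax indices for exact gradient routing.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8 with bias correction.
* Inference disables dropout and is bitwise deterministic; duplicate
  inputs give identical outputs.
* The softmax is computed with max-subtraction; cross-entropy clips
  probabilities at 1e-12.
* Degenerate inputs: empty masks error in `crop_to_roi()` and
  `compute_r_ratio()`; constant images normalize to zero; non-finite
  training loss aborts with a diagnostic rather than continuing.

## Desk-scale testing profile and limitations

The clinical experiment (96 patients, 64³-scale inputs, 1000 epochs,
tenfold CV, five variants) is far beyond a single-CPU test budget. The
shipped tests therefore run a documented reduced profile — 20³ phantom
grids, 12³–16³ ROIs, 2 encoder levels, few epochs, 2–3 folds — and assert
*contracts and orderings* (memorization ability, initial loss at ln 2,
leakage-free folds, asymmetric > FLAIR-only mean out-of-fold accuracy)
rather than clinical numbers. The published confusion tables are verified
as exact arithmetic. One printed value upstream does not survive
recomputation: the anterior/middle-fossa stratum is printed as accuracy
0.89 with counts 38/43, which is 0.8837 and rounds to 0.88; the package
keeps the exact arithmetic.

Known limitations: no DICOM ingestion, no registration optimization, no
skull stripping or bias-field correction, no Grade III tumors, no
anatomically realistic brain background, and no attempt to reproduce the
clinical cohort's accuracy/AUC — the data are not public.
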