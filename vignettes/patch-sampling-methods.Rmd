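---
title: "Patchwise sampling for 3D CNN classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patchwise sampling for 3D CNN classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchcascade)
```

## The problem

Subject-level 3D convolutional networks classify a whole brain volume at
once. On gray-matter density maps (GMDMs) of roughly 10^6 voxels this means
millions of trainable weights fed by a few hundred subjects — a textbook
curse-of-dimensionality setting. Patch-based designs mitigate it: a set of
smaller sub-volumes ("patches") is extracted from each subject's map, a
compact subnetwork learns a representation per patch position, and a
subject-level stage fuses the patch representations into one diagnostic
score (here AD vs. cognitively normal, CN). How the patches are carved out
of the volume — compact cubes on an overlapping grid, elongated slabs along
one axis, or anatomically targeted regions of interest (ROIs) such as the
hippocampi — is a design choice with measurable consequences, and this
package exists to make that comparison reproducible end to end without
access to any restricted imaging data.

## The cascaded classifier

All variants share a VGG-like trunk: four 3^3 same-padded unit-stride
convolutions with 8, 16, 32, 64 channels, each followed by ReLU, L2 weight
decay, and max-pooling. The subject-level baseline pools 3^3/stride-3 first
and then 2^3/stride-2 three times; patch-level subnetworks pool 2^3
throughout because their inputs are already small. Pooling output extents
are the *ceiling* of extent/stride: floor rounding would give 30x38x30
after the first pool of a 91x115x91 input, and the architecture's printed
feature-map sizes (31x39x31, 16x20x16, 8x10x8, 4x5x4) are only consistent
with ceiling division, so the choice is forced by arithmetic. The same
arithmetic forces a single input channel, since the first conv layer has
exactly 224 = 8 x (27 x 1 + 1) parameters.

The FC head of the trunk (1024, 128, 2 with dropout 0.5 after the first
two) is used in two roles: it is the classifier of the subject-level
baseline, and it is the *pretraining* head of every patch-level
subnetwork. For the cascade proper, each patch position gets its own
subnetwork trained from scratch on its patch; afterwards the convolutional
layers are frozen, the final conv feature maps are flattened and
concatenated across patch positions, and a fusion head (2048, 512, 2; ReLU
+ L2 + dropout on the first two) is trained on the frozen features. In this
implementation the freeze is structural: fusion training only ever sees the
precomputed feature matrix, so subnetwork weights are bit-identical before
and after (a property the test suite asserts).

`count_parameters()` implements the closed forms (conv:
`C_out (k^3 C_in + 1)`; dense: `units (fan_in + 1)`) and `build_model()`
instantiates runnable weights whose introspected count must agree exactly.

### The CNN engine

No deep-learning framework is available to R in this project's toolchain,
so the package carries a compact engine of its own, implemented as
vectorized linear algebra: convolutions are an im2col gather followed by a
BLAS matrix product, the input gradient is the transposed convolution
(kernel flipped on every axis), pooling is a reshape/permute plus columnwise
argmax with `-Inf` padding, and optimization is Adam on class-weighted
cross-entropy. Gradients are verified against central finite differences in
the test suite. The engine supports exactly the layer kinds the
architecture specifications use — this is a faithful reimplementation of
the classifier under study, not a general-purpose library.

## Patch geometry

Patch positions on an axis of length `E` for `n` patches of length `p`
follow endpoint-anchored even spacing: start offsets
`round(i (E - p)/(n - 1))`, halves rounded down. This is the unique
symmetric rule that pins the first and last patch to the volume faces and
spreads the rest evenly, and it reproduces the standard partitions of a
91x115x91 map: twelve 48^3 cubes (2x3x2), eight 64^3 cubes (2x2x2), six
91x25x91 coronal slabs (1x6x1). Patch *counts* are explicit configuration
rather than being derived from a stride: published totals for smaller
cubes (28 of 32^3, 72 of 24^3) are below the minimal per-axis covering
products (36 and 80), which suggests patches dominated by empty background
were dropped; since the exact rule is not recoverable, the planner accepts
any counts, audits coverage voxel-by-voxel (`coverage_report()`), and
offers a nonzero-fraction filter as one mechanism that produces such
reduced totals. ROI patches are centered on caller-supplied voxel
coordinates (no atlas is bundled) and clamped into bounds.

`mean_pairwise_distance_mc()` quantifies why patch *shape* matters at fixed
volume: the expected Euclidean distance between two uniform points of a box
is minimized by the cube (Robbins constant, 0.6617 x side), so a 48-voxel
cube at 1.5 mm gives ~47.6 mm while the equal-volume 91x25x91 slab gives
~73.3 mm — voxels that share a patch label are on average much farther
apart in the slab. Sampling is continuous-uniform over the physical box
(not voxel centers), which is the convention that reproduces those
figures; estimates come with standard errors and are exactly
scale-equivariant in the voxel size.

## Synthetic cohorts

Real GMDMs from restricted-access cohorts cannot ship with a package, so
`generate_cohort()` draws volumes with the statistical structure the
analysis pipeline assumes, nothing more:

* a fixed smooth pseudo-anatomy (a table of low-frequency Gaussian bumps
  under a soft envelope, normalized to maximum 1) shared by all subjects —
  the analogue of spatially normalized anatomy;
* per-subject uniform sub-voxel jitter (≤ 1 voxel, default amplitude 0.5)
  applied by evaluating the analytic template at shifted coordinates —
  residual misalignment after normalization;
* multiplicative "atrophy" for AD subjects: intensity scaled by `1 - δ`
  inside a hard sphere with a 2-voxel linear soft edge, at configurable
  sites — modulated gray-matter loss without committing to anatomy;
* optional disease heterogeneity: a configured fraction of AD subjects has
  the *first* listed site spared entirely, mimicking patients whose primary
  region is preserved;
* additive i.i.d. Gaussian noise after atrophy, then clipping to
  `[0, 1 + 5 noise_sd]` (density maps are nonnegative).

Defaults are chosen once: volumes of 121x145x121 voxels at 1.5 mm (the
pre-crop grid of normalized maps), AD fraction 0.45 (the case-control
imbalance typical of such cohorts), noise SD 0.05 against a unit-max
template, background length scale 12 mm, and a mirrored pair of
medial-temporal-like sites with δ = 0.3. No quantitative effect-size ground
truth exists for real GMDMs, so δ is an honest free parameter, not a
calibration to AD.

What passing tests on these cohorts do show: the pipeline's plumbing and
statistics behave as specified, signal injected at a known site is
recovered by models whose patches see the site and not by models whose
patches do not, and performance responds monotonically to effect size. What
they cannot show: anything about absolute accuracy on real ADNI-class data
— real anatomy, scanner effects, registration error and disease
heterogeneity are all richer than this generator.

## Evaluation protocol

Splits are stratified 70/10/20 with per-class largest-remainder
apportionment (187 AD / 229 CN gives 131/19/37 and 160/23/46), randomized
per repetition. The test set is balanced by *matched undersampling*: for
each AD subject, in ascending subject-id order, the unused CN subject with
the smallest mean voxel-wise absolute intensity difference is kept — a
greedy, without-replacement rule that retains exactly the controls hardest
to tell apart from patients. (A globally optimal assignment is *not*
computed; the greedy order is the deterministic reading of
one-instance-per-patient selection, and matching without replacement is
implied by exact balance.) Training uses balanced class weights
`N/(2 N_c)`, Adam at 1e-4, batch 24, dropout 0.5, up to 300 (subject-level)
or 200 (patch-level) epochs with early stopping after 20 non-improving
validation epochs; the monitored metric is validation loss by default
(configurable to accuracy, since only "the validation metric" is
specified). Metrics are ACC, SEN, SPE, F1 = 2TP/(2TP+FP+FN), and rank-based
AUC (ties counted 1/2), with AD as the positive class and threshold 0.5 on
the AD probability.

The whole protocol — split, optional stratified halving of the training
set, matched undersampling, training of every condition on identical
splits, metric computation — is repeated (20 times in the full design) with
all randomness derived from a master seed and the repetition index. Because
every condition within a repetition sees identical data, the resulting
accuracy table is a complete within-subject design, analyzed by one-way
repeated-measures ANOVA with Mauchly's sphericity test, Greenhouse-Geisser
correction when sphericity is rejected at 0.05 (both p-values are always
reported), and Tukey studentized-range post hoc contrasts on the
within-subject error term. The implementation is the closed-form textbook
decomposition and is cross-checked in the tests against an independent
general-purpose implementation (`car::Anova`) to full precision.

## Numerical and design choices

* **Crop placement.** The 121x145x121 → 91x115x91 background crop is
  centered (left margin floor of the total margin). A data-driven tightest
  box is also expressible via the patch machinery, but centered is the
  default because symmetric background removal is the natural reading.
* **Smoothing boundary.** Gaussian smoothing (sigma = FWHM/2.355 per axis,
  kernel truncated at 4 sigma and renormalized) reflects at boundaries,
  which conserves total intensity and avoids darkening map edges.
* **Tie-breaks.** Even-spacing offsets round halves down; matched
  undersampling breaks distance ties toward the smaller CN id; grid search
  breaks CV-accuracy ties toward the smaller learning rate, then batch
  size.
* **Degenerate inputs.** Pooling never collapses an axis under ceiling
  rounding; a single-patch "grid" must equal the volume if coverage is
  demanded; boxes with some zero extents reduce the Monte-Carlo distance to
  its lower-dimensional value, and an all-zero box is rejected.
* **Early stopping bookkeeping.** Training stops at the first epoch whose
  distance from the last improvement equals the patience; the returned
  model is the best-validation checkpoint, not the last.
* **Heterogeneity sampling.** The spared subset is an exact
  `round(fraction x n_AD)`-sized random sample, so fraction 1 spares every
  AD subject deterministically.

## The reduced-scale study preset

`desk_scale_preset()` is the configuration under which the package's
statistical claims are exercised continuously: 28x34x28-voxel cohorts
(n = 60, balanced classes), a single radius-4 atrophy site, 16^3 ROI
patches (the smallest the subnetwork contract allows), conv channels
2/4/8/16 with 32/16/2 and 32/16/2 heads, patch intensities standardized by
training-set statistics, Adam at 3e-3, batch 16, ≤ 35 epochs with patience
15, dropout 0.2. These optimizer settings were chosen because the
full-scale settings are matched to a far larger problem: at this miniature
scale the 1e-4 learning rate and 0.5 dropout leave the network in its
initial plateau for most of a short budget, while 3e-3/0.2 converges
reliably across initializations. The preset ships two ready conditions —
a patch covering the atrophy site and a disjoint, site-free patch — which
is the minimal pair that makes the location-sensitivity of patch sampling
testable: the covering condition should dominate, a zero-effect cohort
should hover at chance, and accuracy should be nondecreasing in δ. Those
three properties, over five cohort seeds, are exactly what the acceptance
suite asserts; problem sizes were fixed with the suite's single-CPU budget
in mind and are stated here as the package's own testing choice.

## Known limitations

* The engine is CPU-bound, single-threaded R: full-size (91x115x91,
  5.4 M-parameter) training is expressible but not practical; the package
  reproduces the full-size *architecture arithmetic* exactly and the
  *training dynamics* at reduced scale.
* The synthetic generator makes no attempt at anatomical realism, scanner
  or site effects, or the upstream segmentation/normalization pipeline; its
  volumes enter the workflow where already-normalized maps would.
* Patch-count ambiguity for 32^3 and 24^3 grids is surfaced, not resolved:
  counts are configuration, and the nonzero filter is one plausible
  mechanism, not a claim about how any published total arose.
* The hippocampus ROI coordinates are caller-supplied; no atlas lookup is
  provided.
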