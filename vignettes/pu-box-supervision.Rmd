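---
title: "Segmenting from boxes: the positive-unlabeled training model"
author: "puboxseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting from boxes: the positive-unlabeled training model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puboxseg)
```

## The problem

Voxel-level tumor masks are the costliest annotation a segmentation model
can demand.  A 3D bounding box around the tumor is far cheaper to draw, but
it is a *corrupted* label: every voxel outside the box is genuinely
background, while the box interior mixes tumor with background.  Training a
network that treats the box as a mask ("naive box supervision") therefore
learns a systematic error: background voxels near the tumor look exactly
like background voxels inside the box, so the network inflates its
predictions toward the box and over-segments.

`puboxseg` instead casts box supervision as positive-unlabeled (PU)
learning.  The voxels outside the box are *positively labeled* samples of
the background class; the voxels inside the box are *unlabeled*.  With a
class prior $\pi_p$ — the proportion of background voxels — the risk of a
classifier $f$ under the true (unknown) voxel labels can be estimated from
these two populations alone.

## The risk estimator

Write $R_p^+$ for the expected loss of calling a background voxel
background, $R_p^-$ for the expected loss of calling a background voxel
tumor, and $R_u^-$ for the expected loss of calling an *unlabeled* voxel
tumor.  Because the unlabeled distribution is the $\pi_p$-mixture of the
two classes, the supervised risk decomposes as

$$R_{PU} = \pi_p R_p^+(\theta) + R_u^-(\theta) - \pi_p R_p^-(\theta),$$

which is unbiased but unbounded below: a flexible network can drive the
empirical correction term $\hat R_u^- - \pi_p \hat R_p^-$ negative by
memorizing the unlabeled sample, which is precisely overfitting.  The
non-negative variant clamps it:

$$R_{PU}^{nn} = \pi_p R_p^+(\theta) + \max\{0,\; R_u^-(\theta) - \pi_p
R_p^-(\theta)\}.$$

Optimization follows the gradient-switching schedule: while the empirical
correction stays above $-\beta$ the optimizer (ADAM) descends the full
clamped objective with step scale $\eta$; when it falls below, the step
descends $\pi_p \hat R_p^- - \hat R_u^-$ — pushing the correction back up —
with the discounted scale $\gamma\eta$.  The operating point is
$\pi_p = 0.75$, $\gamma = 1$, $\eta = 0.5$, $\beta = 0$; all four are
exposed in `pu_loss_config()`.  $\eta$ is interpreted as a multiplicative
scale on the ADAM step size, so the discounted branch is a temporary
learning-rate reduction, not a second optimizer.

Two conventions had to be pinned where the formulation is ambiguous:

* **Averaging.** Each empirical term is averaged over its own label group
  (positives for $\hat R_p^\pm$, unlabeled for $\hat R_u^-$), the
  convention of the non-negative PU estimator; dividing every term by the
  shared batch size instead would double-weight the class prior.  The
  shared-$n$ variant remains available as
  `pu_loss_config(averaging = "shared")` for comparison.
* **Signs.** Losses are standard non-negative cross-entropies, with the
  *background* as the positive class (label 0) and tumor as the negative
  class (label 1).  `voxel_ce()` evaluates them in softplus form, so
  saturated logits neither overflow nor round the loss negative.

Unbiasedness is not assumed, it is tested: on a finite population with
known labels and a fixed classifier, the mean of `pu_risk()` over 500
PU-resampled batches must sit within three Monte-Carlo standard errors of
the fully supervised risk.

## From volumes to batches

Volumes are 4-channel (FLAIR, T2, T1, T1ce) NIfTI images.  Intensities are
z-scored per channel over *brain voxels only* — the black background
outside the brain is exactly 0 and stays 0 — using the population standard
deviation.  Boxes are tight axis-aligned bounding boxes of the reference
mask (0-based, half-open coordinates, so a box composes directly with
array slicing); an optional symmetric margin loosens them, since "roughly
covering" boxes are not precisely specified.  The class prior can also be
recomputed from the box geometry with `class_prior()` instead of using the
fixed 0.75.

Training patches are cubic windows centered on sampled voxels: a fixed
number of candidate centers is drawn uniformly over the volume, tagged by
the region holding the center (S1 inside the box, S0 outside), and
stratified down to `n_selected` patches at an exact 0.8/0.2 S1/S0 split.
Each patch carries box-derived voxel labels: S1 patches the box indicator
(zero-padded where the window leaves the box), S0 patches all zeros.  Even
patch sides use the floor-center convention.  The network input stacks two
scales per modality — the native window and a twice-larger context window
trilinearly resized down — giving 8 channels for 4 modalities.

Mini-batches are stratified: each batch contains S1- and S0-tagged patches
in the pool's proportion, so both label classes are always present and the
three risk components are always defined.  This refines plain shuffling
(which would occasionally produce single-class batches at desk-scale batch
sizes) without changing the objective.  Large mini-batches are evaluated
as accumulated micro-batches of 8 (identical gradients, bounded memory).
The batch size matters beyond throughput: the branch decision compares the
empirical correction term against $-\beta$ per batch, and with small
batches that estimate is noisy enough to flip the branch on every other
step, leaving the unlabeled voxels with no net gradient; at batch 64 the
decision is stable.

## The network

A 3D U-Net with one down-sampling stage fewer than the reference
architecture, on the grounds that aggressive pooling erases small-structure
edges.  Each stage is two 3×3×3 convolution + leaky-ReLU units (slope
0.01, so no filter of a deliberately narrow network can die at
initialization); 2× max pooling down, nearest-neighbour up-sampling with
skip concatenation back up, and a final 1×1×1 convolution to one logit per
voxel.  The logit head is initialized to exactly zero: every voxel starts
at probability 0.5, so the early branch decisions of the PU schedule —
which respond to the logit distribution — carry no seed-dependent skew.
(`build_network(head_init = "random")` restores a conventional random
head.)  The sigmoid lives inside the losses and probability maps, not the
network.

Normalization is configurable and **off by default**.  Instance
normalization — the common recipe in this family — standardizes each
channel within each patch and thereby erases the patch's absolute
intensity level.  When the foreground is distinguished chiefly by a global
intensity shift (z-scored MR, and especially piecewise-constant phantoms),
that cue is load-bearing: with instance norm enabled, a patch lying wholly
inside a uniform bright region becomes indistinguishable from one inside
uniform background, and both training modes over-segment drastically.
`network_config(norm = "instance")` restores the conventional recipe for
data where texture, not level, carries the signal.

The forward/backward stack is hand-written (im2col + GEMM convolutions,
pooled indices cached for the backward pass) and templated on precision:
double precision backs finite-difference gradient checks at $10^{-6}$
accuracy; single precision is the training default.  Everything is
single-threaded and deterministic, so a fit is bit-reproducible from its
seed.

Whole-volume inference tiles the volume at stride $d/2$ and averages
sigmoid probabilities over overlapping tiles; masks are thresholded at 0.5
and interior cavities are filled (6-connectivity flood from the border).

## The phantom generator

Desk-scale testing needs volumes whose true masks are known.  A phantom is
a spherical "brain" (baseline intensity 1, radius 0.8 of the half-extent)
in an exactly-zero background, carrying one tumor built as a union of 1–3
overlapping axis-aligned ellipsoids (semi-axes 6–12 voxels at the default
64³ shape) — a deliberately non-box-shaped object, so the box interior
genuinely mixes both classes.  Each channel adds its own tumor contrast
(defaults 1.5, 1.2, −0.4, 0.8, emulating FLAIR/T2-bright, T1-dark,
T1ce-moderate tumors) and Gaussian noise of sd 0.2 inside the brain.
Cohorts jitter tumor size, position, lobe count and contrast (±20%)
through seeded randomization.

What the phantom does *not* emulate: MRI bias fields, texture, partial
volume effects, multi-site intensity variation, or tumor sub-regions.
Passing the recovery experiment therefore shows that the estimator
recovers sub-box structure when the class-conditional intensity model
holds; it does not certify performance on clinical data.

## The recovery experiment

`recovery_benchmark()` is the package's headline computation: 30 phantoms;
per replicate seed an 80/20 split; training under both objectives on
identical patches from an identical initialization (200 per patient,
$d = 16$, two-stage network with 2 base filters, mini-batch 64, 3 epochs,
ADAM at learning rate $10^{-2}$ scaled by $\eta$);
evaluation of held-out volumes by Dice,
Hausdorff95 and predicted-volume excess, next to the learning-free
region-growing baseline (6-connected flood from the box center, admitting
neighbours within 0.5 of the running region mean in normalized gray
levels); three replicate seeds averaged.  The expected signature, which
the test suite asserts, is the one the method is built for: PU training
beats naive box supervision on held-out Dice, and the naive model's
predicted volume overshoots the true tumor volume by more, because it
segments toward the box.

**The box margin and the prior must agree.**  In the PU decomposition,
$\pi_p$ is the positive-class fraction of the population the *unlabeled*
sample is drawn from — the box interior.  A perfectly tight box around an
ellipsoidal tumor is only about half background, so pairing it with
$\pi_p = 0.75$ overstates the contamination; the clamp then fires
persistently and training stalls at an underfit equilibrium well below
even the naive baseline.  The estimator degrades gracefully in the other
direction (a prior slightly below the true background fraction merely
leaves a little naive-ward bias), so the benchmark derives its
"roughly covering" boxes with the smallest integer margin at which the
cohort's mean in-box background fraction reaches the operating prior —
margin 3, giving 0.79 against $\pi_p = 0.75$ at the default geometry.
`puboxseg(box_margin = )` exposes the same control for other cohorts, and
the residual signature of the mismatch is visible in the results: the PU
model under-segments mildly while the naive model over-segments toward
the box by a multiple.

Problem sizes here are the package's desk-scale choices: the phantom task
is a low-dimensional intensity-contrast problem, and 2 base filters
suffice for it while keeping the full 6-training experiment comfortably
runnable on one CPU; `base_filters = 8` remains the configuration default
for anything less synthetic.  The full-scale operating point of the
original setting (48³ patches, batch 64, 5 epochs, 200 patches from
40 000 candidates) is reachable through the same configuration objects.

## Evaluation conventions

* Dice of two empty masks is 1; of an empty prediction against a nonempty
  truth, 0.
* Hausdorff distances are max–min distances between foreground voxel
  centers scaled by the physical spacing.  (One printed form of the
  directed distance in the source literature reads as max–max, which would
  be the set diameter; the prose definition — distance to the *nearest*
  point of the other set — is implemented.)  Hausdorff95 takes the 95th
  percentile of each directed nearest-distance profile (linear
  interpolation between order statistics, `quantile` type 7) before the
  symmetric max.  Undefined distances (empty sets) are recorded as missing
  and excluded from means with their count reported, never coerced to 0.
* Surface-only point sets are an option (`surface = TRUE`) that leaves
  results for solid masks unchanged while shrinking the distance
  computation.
* `evaluate_cohort()` aggregates five seeded random 80/20 splits and
  reports mean ± sd across folds, skipping (with a warning) folds whose
  evaluation set holds no tumor.

## Degenerate inputs and tie-breaks

Constant brain channels refuse to normalize (zero variance); empty masks
refuse to produce boxes; boxes covering the whole volume refuse a class
prior (it would be 0); single-class voxel batches raise an error that
points at sampler-level stratification rather than silently returning a
partial risk.  Max-pooling breaks ties toward the first voxel in x-fastest
order; the region-grow queue is FIFO — both pinned so results are
bit-stable.  Out-of-volume voxels in patches are zeros, matching the
zero-background convention.

## Known limitations

The nnPU correction assumes the labeled positives are drawn from the same
class-conditional distribution as the positive fraction of the unlabeled
data.  Box supervision violates this mildly — background *inside* the box
is necessarily near the tumor, while labeled background is everywhere
outside — and the residual bias is visible in the experiment: PU training
still over-segments slightly; it just over-segments much less than the
naive baseline.  The class prior is treated as known (0.75 by default);
estimating it from data is out of scope.  Patch sampling assumes the box
is small relative to the volume, so uniformly drawn candidates populate
both regions; for boxes approaching the volume size the sampler errors out
rather than silently unbalancing.
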