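# puboxseg — weakly supervised 3D segmentation from bounding boxes

`puboxseg` trains a volumetric tumor segmentation network when the only
annotation available is a **3D bounding box** per patient, not a
voxel-level mask.  It is aimed at medical-imaging researchers who want to
study weak supervision on multimodal MR volumes (FLAIR, T2, T1, T1ce)
without paying for expert voxel annotation, and at methodologists who want
a compact, fully seeded testbed for positive-unlabeled (PU) segmentation
objectives.

## The idea

A box annotation splits a volume into two regions: outside the box
(**S0**), where every voxel is known background, and inside the box
(**S1**), where tumor and background mix.  Treating the box as a mask
("naive box supervision") mislabels the background inside the box and the
trained network over-segments toward the box.

`puboxseg` instead treats background as the *positive* class (label 0) and
the box interior as *unlabeled*, and trains on the non-negative PU risk:
with class prior pi_p (the background fraction, operating value 0.75),

    R_pu  = pi_p * R_p+  +  R_u-  -  pi_p * R_p-          (unbiased)
    R_nn  = pi_p * R_p+  +  max{0,  R_u-  -  pi_p * R_p- } (clamped)

where `R_p+` / `R_p-` are the mean losses of calling a labeled background
voxel background / tumor, and `R_u-` is the mean loss of calling an
unlabeled voxel tumor.  Optimization uses ADAM with a gradient-switching
schedule: while the empirical correction `R_u- - pi_p * R_p-` stays above
`-beta` the full clamped objective is descended with step scale `eta`;
when it dips below, the step instead descends `pi_p * R_p- - R_u-` with
the discounted scale `gamma * eta` (defaults: `beta = 0`, `gamma = 1`,
`eta = 0.5`).

Around the estimator the package provides the full pipeline: NIfTI volume
I/O with brain-masked z-score normalization, box derivation from reference
masks, stratified two-scale patch sampling (0.8/0.2 from S1/S0), a compact
3D U-Net with hand-written forward/backward passes (Rcpp/Armadillo),
sliding-window inference, Dice / Hausdorff / Hausdorff95 evaluation with
fold aggregation, a learning-free region-growing baseline, and a seeded
multimodal phantom generator so everything runs at desk scale.

## Worked example

```r
library(puboxseg)

# a small seeded cohort of 4-channel phantoms with known tumor masks
cohort <- generate_cohort(10, phantom_spec(), seed = 11)

# fit from boxes only (derived from the masks with a loose margin;
# the masks themselves are never used for gradients)
fit <- puboxseg(cohort[1:8], mode = "pu",
                net = network_config(base_filters = 2),
                control = train_config(batch_size = 64, learning_rate = 1e-2),
                box_margin = 3, seed = 5)
print(fit)
#> puboxseg model (mode = pu)
#>   8 patients, 75 training steps over 3 epoch(s)
#>   final objective: 0.4452  (discounted-branch steps: 30/75)

# segment a held-out patient and score it against the known mask
mask <- predict(fit, cohort[[9]]$volume, type = "mask")
dice(mask, cohort[[9]]$mask)
#> [1] 0.5794849
```

The headline experiment — PU versus naive box supervision versus region
growing on 30 phantoms, three replicate seeds, 18 held-out evaluations —
is one call:

```r
bench <- recovery_benchmark(seed = 1)
print(bench)
#> recovery_benchmark: 30 phantoms, 3 replicate seed(s), 18 held-out evaluations
#>   held-out Dice     : PU 0.746 | naive 0.370 | region-grow 0.766
#>   Dice margin (PU - naive): 0.376
#>   volume excess     : PU +0.29 | naive +3.45 (fraction of true volume)
#>   Hausdorff95 (mm)  : PU 2.31 | naive 6.38
```

Read it as: trained from identical boxes, patches and initializations, the
PU objective doubles the held-out whole-tumor Dice of the naive baseline,
and the naive model predicts 4.5x the true tumor volume (it segments
toward the box) while the PU model stays within ~30% of it.  The
intensity-based region grower does well here because phantom tumors are
piecewise-constant; it degrades on textured data, which is exactly what it
cannot model and the learned methods can.

A command-line interface over the same pipeline lives in
`inst/cli/puboxseg` (subcommands `simulate`, `train`, `predict`,
`evaluate`, configured by YAML).

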