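Package: puboxseg
Title: Weakly Supervised 3D Segmentation from Bounding Boxes via
    Positive-Unlabeled Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains volumetric tumor segmentation networks from 3D bounding
    box annotations instead of voxel-level masks.  Voxels outside the box are
    treated as positively labeled background and voxels inside as unlabeled,
    and a small 3D U-Net is optimized with a non-negative positive-unlabeled
    risk estimator with a gradient-switching schedule; a naive box-supervised
    baseline and a region-growing baseline are included.  Ships a seeded
    multimodal phantom generator, NIfTI volume handling with brain-masked
    z-score normalization, stratified box-region patch sampling with
    two-scale inputs, sliding-window inference, and Dice / Hausdorff /
    95th-percentile Hausdorff evaluation with fold-aggregated reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
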