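Package: sinusseg
Title: Coarse-to-Fine 3D U-Net Segmentation of the Maxillary Sinus in CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic volumetric segmentation of the maxillary sinus from
    cone-beam computed tomography (CBCT) scans using a two-stage (coarse-to-fine)
    pair of 3D U-Nets trained with a weighted binary cross-entropy loss. Provides
    DICOM-series and NIfTI volume input, isotropic resampling, a synthetic
    CBCT-phantom generator with paired ground-truth sinus masks, network training
    with spatial augmentation and early stopping, patch-based full-resolution
    inference with largest-connected-component post-processing, isosurface mesh
    extraction with volume-preserving smoothing and STL export, and the standard
    segmentation evaluation metrics (Dice, IoU, 95th-percentile Hausdorff
    distance and RMS surface distance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
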