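Package: autoconfidence
Title: Reference-Free Voxel-Wise Confidence Estimation for Multi-Organ
    Auto-Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Adversarially trained, model-agnostic quality assurance for
    organ-at-risk auto-segmentation. A compact 2D U-net generator proposes
    segmentations while a shallow residual encoder-decoder discriminator
    learns, via focal log losses, to predict the per-voxel probability that
    a segmentation disagrees with the gold standard. The trained
    discriminator yields reference-free confidence maps for segmentations
    from any source. Includes a multi-organ phantom simulator, synthetic
    error injection (rigid, thin-plate-spline, class perturbation, organ
    removal), intelligent edge removal and geometric distance correction
    post-processing, confusion-based evaluation metrics (MCC, FPR, FNR,
    FP/FN, DSC), and four-colour map rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
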