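Package: gcgmm
Title: Appearance-Constrained Interactive Tumour Segmentation for DCE-MRI
    Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Semi-automatic segmentation of enhancing lesions from dynamic
    contrast-enhanced MRI by fusing GrowCut cellular-automaton segmentations
    of eight temporal feature images with a tumour-specific multi-parametric
    Gaussian mixture labeling (GCGMM), together with the surrounding study
    machinery: a synthetic DCE phantom generator with rater-style input
    variants, automatic seed-stroke extraction from contour or ROI inputs, a
    fuzzy c-means baseline, segmentation accuracy and reproducibility
    metrics (Dice, surface distances, volume ratio, RMS coefficient of
    variation, intraclass correlation), 36 first-order and Haralick texture
    features, and a SMOTE-balanced random-forest classification stage with
    leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    pROC,
    randomForest,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
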