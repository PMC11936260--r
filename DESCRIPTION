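Package: roscope
Title: Image-Based Quantification and Deep-Learning Classification of
    Microglial Reactive Oxygen Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end platform for assessing reactive oxygen species
    (ROS) in single microglial cells from two-channel confocal z-stacks.
    Generates labelled synthetic actin/ROS stacks with ground truth,
    quantifies per-cell CellROX-style measures (area, mean, max, integrated
    density, raw integrated density) with Welch two-sample comparisons,
    preprocesses z-slices (min-max normalization, 256x256 area resize,
    histogram equalization, z-slice augmentation, stratified train/val/test
    splits), trains compact two-convolution CNN classifiers for treatment
    (CBD vs control) and condition (LPS/GP120/Abeta42) with Adam and
    cross-entropy, evaluates them (accuracy curves, confusion matrices,
    ROC/AUC), and explains predictions with Grad-CAM saliency maps plus an
    edge-saliency statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
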