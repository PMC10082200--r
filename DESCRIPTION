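Package: ctroi
Title: Organ Localization in CT Volumes by Orthogonal Projection
    Classification and Intensity Clustering
Version: 0.1.0
Authors@R:
    person("ctroi", "developers", email = "ctroi@example.org",
           role = c("aut", "cre"))
Description: Locates kidneys and spleens in abdominal CT volumes by
    classifying slices in the three orthogonal projections (sagittal,
    coronal, axial) with small convolutional networks, intersecting the
    per-axis decisions into a 3D region-of-interest cube, and recovering
    the organ contour inside the cube by intensity K-means clustering with
    morphological post-processing.  Ships a synthetic CT phantom generator
    for fully reproducible training and evaluation, and the standard
    volumetric segmentation metric suite (F1/Dice, sensitivity, precision,
    VOE, RVD, ASSD, MSSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse,
    yaml
Config/testthat/edition: 3
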