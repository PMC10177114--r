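Package: rotface
Title: Rotation-Aware Livestock Face Detection and Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A one-stage anchor-based convolutional detector that jointly
    predicts an animal face's bounding box and its in-plane rotation angle,
    coded as an absolute value plus a direction flag to avoid the 180-degree
    boundary discontinuity. Includes the multi-level anchor machinery, a
    lightweight 14-layer convolution-batchnorm-activation backbone with a
    top-down feature pyramid neck and shared detection head, the four-term
    training loss with dual-dataset angle masking, angle-aware augmentation
    (90-degree rotation, flips, image tiling), a synthetic oriented-face
    scene generator for fully reproducible experiments, detection metrics
    (precision/recall/F1, average precision, average angle difference), and
    face normalization by rotate-crop-scale. All network computation runs on
    the CPU through compiled im2col/GEMM kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
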