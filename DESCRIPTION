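Package: nucseg
Title: One-Stage Nucleus Instance Segmentation with Deformable Multi-Level Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nucleus instance segmentation for H&E-stained histopathology
    patches using a one-stage, location-based mask head on top of a residual
    backbone with deformable convolutions and a balanced (non-local refined)
    feature pyramid. Includes a synthetic nucleus-scene generator with
    COCO-dialect annotations, a photometric augmentation channel, SGD training
    with focal and dice losses, and a mask-level COCO-style evaluator
    (AP/AR over IoU 0.50-0.95, precision-recall curves). The convolutional
    core, including the deformable convolution operator and its gradients, is
    implemented in C++ with a compact reverse-mode autodiff layer in R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
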