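Package: cellsage
Title: Lightweight Attention-Augmented Convolutional Classification of
    Histopathology Patches
Version: 0.1.0
Authors@R:
    person("CellSage", "Maintainers", email = "maintainers@cellsage.dev",
           role = c("aut", "cre"))
Description: A self-contained implementation of a lightweight convolutional
    network for binary (benign versus malignant) classification of
    hematoxylin-and-eosin histopathology image patches, combining a
    multi-scale convolutional feature extractor, a depthwise-separable
    convolution stack, and a convolutional block attention module (CBAM).
    Includes stain-appearance normalization, patient-stratified data
    partitioning and cross-validation, the full training recipe (Adam,
    cosine annealing with warm restarts, early stopping, class-weighted
    binary cross-entropy), Grad-CAM saliency rendering, analytic
    parameter/MAC profiling with baseline architecture oracles, and a
    synthetic histology-patch generator so the entire pipeline is testable
    at desk scale without external data. All tensor operations are
    implemented on base R and BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
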