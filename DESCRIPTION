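Package: koadapt
Title: Adaptive Early Stopping and Gradual Cross-Entropy for Knee
    Osteoarthritis Grading
Version: 0.1.0
Authors@R: person("koadapt", "developers", role = c("aut", "cre"),
    email = "koadapt@example.org")
Description: A desk-scale image-classification pipeline for ordinal
    Kellgren-Lawrence grading of knee radiographs. Implements an adaptive
    early-stopping rule whose patience threshold is the running average of
    successive validation-loss differences, applied at both the epoch
    (macro) and batch (micro) level; a gradual cross-entropy loss that
    rescales aborted epochs by the consumed-example fraction; a symbolic
    DenseNet-169 layer plan with verifiable tensor-size calculus and a
    trainable pure-R instantiation; augmentation-based class balancing,
    stratified splitting and 5/3/2-class label regrouping; micro- and
    macro-averaged confusion-matrix metrics; and a synthetic radiograph
    generator so the full pipeline runs without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
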