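Package: lcml
Title: Layerwise Complexity-Matched Learning and Neural Alignment Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for training a two-stage convolutional encoder with per-layer
    feature-contrastive objectives whose input complexity (patch size, spatial
    deformation strength) is matched to each stage's capacity, together with an
    evaluation suite for alignment with early visual cortex: a steerable-pyramid
    V1 baseline with simple/complex-cell nonlinearities and energy pooling,
    partial-least-squares neural predictivity with cross-validation, texture
    modulation statistics against spectrally-matched noise, and generators for
    synthetic texture stimulus sets and simulated V2-like neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite
Config/testthat/edition: 3
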