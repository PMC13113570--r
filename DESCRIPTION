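Package: lesionkit
Title: Dermoscopic Lesion Segmentation, Feature Extraction, Metaheuristic
    Feature Selection and Hybrid Classification
Version: 0.1.0
Authors@R:
    person("lesionkit", "developers", email = "lesionkit@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a hybrid
    dermoscopy analysis pipeline: contrast-limited adaptive histogram
    equalization (CLAHE) and adaptive local Wiener filtering for
    preprocessing; a selective-kernel U-Net (SK-UNet) with
    squeeze-and-excitation residual encoder blocks for lesion
    segmentation; handcrafted color (RGB/HSV), texture (GLCM Haralick
    descriptors, local binary patterns) and shape (dispersity,
    saturation, roundness) features; fossa-optimization-algorithm (FOA)
    wrapper feature selection; and a hybrid 1D-CNN-GRU classifier.
    Includes seeded synthetic lesion-image and feature-table generators
    so every stage can be exercised without external data, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
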