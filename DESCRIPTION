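Package: mclseg
Title: Semi-Supervised Multi-Decoder Consistency Segmentation for Microscopic Hyperspectral Pathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-supervised tumor segmentation of microscopic
    hyperspectral pathology images. Implements a shared-encoder / multi-decoder
    U-Net in which auxiliary decoders receive feature-noise-perturbed bottleneck
    representations, pseudo-labels are produced by a sharpen-then-argmax
    ("Soft-Hard") scheme, and decoders supervise one another through a pairwise
    multi-consistency objective combining cross-entropy and Dice losses under a
    Gaussian warm-up schedule. Includes PCA spectral band reduction, ENVI and
    RDS cube input/output, a seeded synthetic hyperspectral-pathology scene
    generator with ground-truth masks, pixel-level evaluation metrics (overall
    accuracy, average accuracy, Dice, mean IoU), tiled full-scene inference,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
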