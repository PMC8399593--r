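Package: neovaseg
Title: Semantic Segmentation of Retinal Neovascularization in Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for detecting and
    localizing neovascularization lesions in retinal fundus images by per-pixel
    semantic segmentation. Provides a synthetic fundus phantom generator with
    exact ground-truth masks (branching vessel trees, optic disk, tortuous
    neovascular tangles), green-channel extraction and contrast-limited
    adaptive histogram equalization (CLAHE) preprocessing, deterministic
    patch tiling and flip augmentation, a compact 42-layer encoder-decoder
    convolutional network with residual downsampling blocks and a depth
    concatenation skip, stochastic-gradient-descent-with-momentum training
    with validation-patience early stopping, and two-level evaluation
    (per-pixel segmentation metrics and patch-level classification) including
    Dice and Jaccard coefficients with explicit undefined-value semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
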