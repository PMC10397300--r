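Package: BurnNeXt
Title: Attention-Based Residual Networks for Burn Depth Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and evaluates BuRnGANeXt-50, a slimmed ResNeXt-50
    convolutional network with residual, channel and spatial attention modules
    for classifying human burn images by depth (superficial, deep dermal, full
    thickness) and by clinical grafting decision (graft versus non-graft).
    Includes a declarative network builder with trainable-parameter accounting,
    an R/C++ training engine (grouped convolutions, batch normalisation,
    local response normalisation, Leaky ReLU, Adam), a synthetic burn-image
    generator emulating the colour semantics of the three burn depths, flip and
    rotation augmentation, stratified fivefold cross-validation, and a
    confusion-matrix metric suite (accuracy, precision, recall, F1, sensitivity,
    specificity) with ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    png,
    jpeg,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
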