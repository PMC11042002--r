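Package: diatomnet
Title: Lightweight Inception Networks for Diatom Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements DiatomNet, a lightweight convolutional neural
    network with three dimension-reduced inception modules for classifying
    diatom species from light-microscopy images, together with the full
    surrounding pipeline: a declarative architecture dialect with analytic
    shape propagation and learnable-parameter accounting, polygon-based
    crop extraction with horizontal normalization, flip augmentation,
    stratified dataset splitting, SGD training with early stopping,
    support-weighted multiclass evaluation, and activation-map
    interpretability.  A procedural generator of diatom-like annotated
    micrographs makes every stage testable without external data.  The
    network forward and backward passes are written on dense linear
    algebra kernels (RcppArmadillo), so the package has no deep-learning
    framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    EBImage
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
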