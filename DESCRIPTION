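Package: rapidcat
Title: Rapid Visual Categorization with Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for modelling ultrafast ("is there an animal in this
    scene?") image categorization with convolutional neural networks. Builds
    balanced target/distractor datasets from a hyperonym (is-a) hierarchy of
    semantic synsets, trains and re-trains VGG-style convolutional classifiers
    under several transfer-learning protocols, scores superordinate categories
    by summing post-softmax leaf probabilities over hyperonym paths, prunes
    network depth, and quantifies robustness to rotation, reflection,
    grayscale conversion and patch shuffling, as well as the cross-task bias
    between anti-correlated categories. Includes a procedural image generator
    with controllable category cues so the full pipeline runs at desk scale
    without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    png,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
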