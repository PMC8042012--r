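Package: cytocurve
Title: Learning-Curve Analysis for Single-Cell Leukocyte Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the performance of a small sequential
    convolutional network for single-cell leukocyte classification depends
    on the number of training images. Provides a seeded synthetic
    blood-smear cell image generator with controllable morphological effect
    size, a six-stage 3x3-convolution network with exact parameter
    accounting, a nested incremental tenfold cross-validation protocol with
    flip/rotation augmentation and per-class balancing, ROC/F1 evaluation
    with fold-averaged curves and boxplot summaries, and model
    introspection via gradient saliency maps, layer-wise relevance
    propagation and t-SNE embedding of the penultimate layer.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    cluster,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
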