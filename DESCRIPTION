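Package: histopatch
Title: Comparative Classification of H&E Histopathology Image Patches with
    Handcrafted and Deep Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for comparing classical and
    deep-learning classification of hematoxylin-and-eosin (H&E) histopathology
    image patches. Provides a seeded synthetic H&E-like patch generator with
    nucleus-level ground truth; stain-color normalization by sparse
    non-negative stain separation in optical-density space; a fused 550-d
    handcrafted descriptor (Zernike moments, Haralick texture statistics and a
    joint color histogram); five classical classifiers under stratified
    10-fold cross-validation; a VGG-19-style convolutional network with
    six-block partitioning and block-wise freeze/fine-tune schedules trained
    by stochastic gradient descent; and visual explanation via PCA/kernel-PCA
    embeddings and Grad-CAM heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jsonlite,
    Rcpp,
    EBImage,
    randomForest,
    e1071,
    rpart
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr
Config/testthat/edition: 3
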