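Package: dermocad
Title: Computer-Aided Melanoma Diagnosis from Dermoscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the stages of a melanoma computer-aided
    diagnosis (CAD) pipeline on dermoscopic images: hairline artifact removal by
    grayscale morphological closing and neighbour-intensity inpainting, contrast
    restoration by a multiscale context aggregation network (MCAN) built from
    dilated-convolution residual blocks, lesion segmentation by an atrous
    convolutional network (ACNN), and benign-versus-melanoma classification by a
    compact deep convolutional network (N-DCNN) trained with stochastic gradient
    descent with momentum and weighted cross-entropy. Includes dataset
    preparation (correlation-based deduplication, stratified splitting, random
    oversampling, geometric augmentation), confusion-matrix metrics with ROC/AUC
    and layer-wise parameter counting, and a seeded synthetic dermoscopic image
    generator with pixel-exact hair and lesion ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
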