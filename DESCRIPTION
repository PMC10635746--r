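Package: dsmammo
Title: Evidential Fusion of Texture and Deep Classifiers for Mammographic
    Mass Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid computer-aided diagnosis pipeline for mammogram-like
    grayscale images. Images are denoised with a median filter, contrast
    enhanced by histogram equalization, and the breast region is isolated by
    thresholding and morphological erosion. Two independent classifiers -- a
    multilayer perceptron over gray-level co-occurrence matrix (GLCM) texture
    features and a small convolutional neural network over the images -- each
    emit class-probability triples over benign, malignant and ignorant
    (normal), which are combined with Dempster-Shafer evidence theory into a
    fused, higher-confidence decision. A synthetic phantom generator emulates
    the mammographic phenotypes (smooth-margin benign discs, spiculated
    malignant masses, textured background) so the whole pipeline is testable
    offline, and a cross-validated evaluation layer reports confusion
    matrices, accuracy, sensitivity, specificity and ROC curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    pROC,
    Matrix,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
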