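Package: mriforensics
Title: Detection of Tampered MRI-Like Images with Adversarially Trained
    Feature-Fusion Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting locally manipulated (tumor-inserted or
    tumor-removed) grayscale medical-style images. Provides a synthetic
    brain-phantom corpus generator with ground-truth manipulation masks,
    canonical preprocessing, FGSM and PGD adversarial example crafting for
    robust training, fused handcrafted (HOG) plus deep convolutional
    features, RBF-SVM and convolutional-network base classifiers, an
    AUC-weighted soft-voting ensemble, and a complete evaluation suite
    (confusion metrics, ROC/PR, calibration, probability summaries,
    Wilcoxon signed-rank model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
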