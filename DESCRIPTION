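Package: slidegraph
Title: Two-Step Whole-Slide Gastric Biopsy Classification with Patch Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of a two-step classifier for
    whole-slide images of endoscopic gastric biopsies. A small
    encoder-decoder network trained with dice loss segments abnormal
    tissue per patch and doubles as a feature extractor; the most
    abnormal patches become nodes of a slide graph whose edges connect
    feature vectors closer than a Chebyshev-distance threshold; a graph
    convolutional network trained with focal loss emits four-tier
    probabilities (NED, LGD, HGD, IIN). Includes a synthetic slide
    generator with per-pixel category masks and center-specific stain
    shifts, stain normalization, an NED-screening mode whose threshold
    is calibrated to guarantee 100% negative predictive value on the
    calibration set, and an evaluation battery (confusion matrices,
    sensitivity/specificity/accuracy/NPV, ROC/AUC, Cohen's kappa with
    quadratic weighting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pROC,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    tiff,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
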