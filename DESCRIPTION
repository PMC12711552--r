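Package: subtyper
Title: Two-Stage Whole-Slide Image Subtyping for Cervical Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-stage pipeline for classifying cervical cancer whole-slide
    images (WSIs) into squamous cell carcinoma (SCC) and adenocarcinoma (AC).
    Slides are tiled into non-overlapping patches, screened by a five-step
    quality-control cascade (RGB background, HSV glare, HED pen-mark, Canny
    edge-variance filters, and Vahadane stain normalization), classified at
    patch level by a convolutional network trained with Adam, and aggregated
    to slide level by majority voting or multiple-instance features
    (probability histograms and TF-IDF of patch-prediction tokens) feeding
    class-weighted classifiers. Includes the clinical evaluation stack
    (bootstrap confidence intervals, DeLong AUROC comparison, calibration
    and decision-curve analysis), Grad-CAM explanations, and a synthetic
    H&E-like data generator so the whole pipeline is testable end to end
    without any external images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    MASS,
    rpart,
    randomForest,
    e1071,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
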