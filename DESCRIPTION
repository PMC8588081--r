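Package: neojaundice
Title: Smartphone-Image Screening Pipeline for Neonatal Jaundice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested implementation of a smartphone-image pipeline
    for screening neonatal jaundice. Provides calibration-card white balancing,
    68-point facial-landmark segmentation of the forehead and eye sclerae,
    mean color features in four color spaces (RGB, full-range BT.601 YCbCr,
    CIELab, HSV), four classical classifiers plus a small transfer-learning
    style convolutional branch, and an evaluation protocol with SMOTE class
    balancing, stratified five-fold cross-validation, five performance
    metrics, and the k-fold cross-validated paired t-test for model
    comparison. A seeded synthetic-scene generator emulates the statistical
    structure of the clinical images (skin and scleral yellowing driven by a
    latent transcutaneous bilirubin level, per-image illumination gains, a
    calibration card with a known white patch) so that the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    png,
    e1071,
    rpart,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
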