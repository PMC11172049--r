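Package: waveletDR
Title: Wavelet CNN Grading of Diabetic Retinopathy from Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades diabetic retinopathy severity (ICDR scale 0-4) from retinal
    fundus photographs with a wavelet convolutional neural network: a 2-D Haar
    multiresolution decomposition is woven into a VGG-style convolutional stack
    by channel-wise injection of sub-band planes at matching spatial scales,
    features are read out by global average pooling, and classical heads
    (SVM, random forest, XGBoost, softmax) classify the pooled features.
    Includes the full preprocessing chain (contrast enhancement, resize,
    crop, flip), augmentation-based class balancing, stratified splitting,
    a one-vs-rest ROC/AUC evaluation suite, and a deterministic synthetic
    fundus-phantom generator so the whole pipeline is testable without any
    external image corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite,
    e1071,
    randomForest,
    xgboost,
    nnet,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
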