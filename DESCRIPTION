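Package: nodboost
Title: Boosted Self-Normalizing Multiview Convolutional Networks for Lung
    Nodule Candidate Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies lung nodule candidates in CT volumes with an AdaBoost
    ensemble of small self-normalizing multiview convolutional neural
    networks. Provides a seeded synthetic CT phantom generator (Gaussian-blob
    nodules and tubular vessel confusers), multiview patch extraction around
    candidate voxels with spline resizing to a common network input size, a
    SELU-activated convolutional base learner trained with sample-weighted
    binary cross-entropy, the AdaBoost weight-update and weighted-voting
    machinery, and evaluation utilities (confusion matrix, accuracy,
    sensitivity, specificity, ROC/AUC, stratified splits and k-fold
    cross-validation), plus an end-to-end pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
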