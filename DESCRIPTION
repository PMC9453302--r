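Package: sleepyEEG
Title: Simulation, Preprocessing, and Classification of Drowsiness EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting driver drowsiness
    (sleepy vs. normal) from multichannel EEG. Provides a synthetic-EEG
    generator built on the linear mixing model X = AS + N with
    alpha-dominant (drowsy) and beta-dominant (alert) source spectra,
    zero-phase band-pass preprocessing and epoch segmentation,
    multiplicative Gaussian-noise data augmentation, band-power and
    common-spatial-pattern (CSP) features with classical baseline
    classifiers, a compact 1-D convolutional network trained by
    mini-batch gradient descent with layer freezing and fine-tuning,
    and an evaluation harness with stratified holdout, 10-fold
    cross-validation, confusion-matrix metrics and ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
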