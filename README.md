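# sleepyEEG

Simulation, preprocessing and classification of drowsiness EEG in R.

Drowsy ("sleepy") and alert ("normal") brain states leave a spectral
signature in scalp EEG: relaxation toward sleep boosts alpha-band power
(8–13 Hz), alertness boosts beta (13–30 Hz). sleepyEEG is an end-to-end,
fully tested pipeline for binary sleepy-vs-normal classification built
around that contrast, aimed at researchers prototyping drowsiness
detectors without access to shareable recordings:

* **Synthetic acquisition model.** Labeled multichannel recordings are
  generated under the linear mixing model `X = AS + N` — narrow-band
  stochastic oscillations plus 1/f background mixed onto 8 channels with
  Gaussian sensor noise — following a 20-subject, 3 × 7-minute-session,
  500 Hz protocol with alpha-dominant (sleepy) and beta-dominant (normal)
  source spectra.
* **Preprocessing.** Zero-phase Butterworth band-pass (1–30 Hz), sliding
  window epoching, per-channel zero-centering, peak-amplitude artifact
  rejection.
* **Augmentation.** Epochs multiplied elementwise by Gaussian noise
  `N(1, sigma^2)` — unbiased in expectation and spectrum-preserving, unlike
  geometric transforms — applied only to training partitions.
* **Classical baselines.** Welch band power and two-class common spatial
  patterns (CSP, solving `C_A w = lambda (C_A + C_B) w`), fed to
  tree / LDA / RBF-SVM / k-NN under identical splits.
* **Compact 1-D CNN.** Three time-axis convolutions (kernels 5, 3, 3) with
  ReLU and max-pooling, two fully-connected layers and a softmax, trained
  by mini-batch SGD (momentum 0.9, base learning rate 0.001) with early
  stopping, layer freezing and fine-tuning. The engine is vectorized base
  R with gradients verified against finite differences.
* **Evaluation harness.** Stratified 80/20 holdout, shuffled stratified
  10-fold CV, confusion-matrix metrics (accuracy, per-class precision and
  F1), ROC/AUC, tidy `tidy()`/`glance()` accessors and `autoplot()`
  methods.

## Worked example

Simulate a small two-group study, preprocess it, and cross-validate an
SVM on band-power + CSP features:

```r
library(sleepyEEG)

es <- session_protocol(n_subjects = 4, n_sessions_per_subject = 1,
                       session_duration = 60) |>
  generate_dataset(seed = 42) |>
  bandpass_dataset() |>
  segment_dataset(window = 2) |>
  zero_center_epochs()
es
#> <epoch_set> 120 epochs (0 augmented), 8 ch x 1000 samples @ 500 Hz
#> label
#> normal sleepy
#>     60     60

cv <- run_cv(es, split_spec("kfold", k = 10, seed = 42),
             classical_model("svm", "bp+csp"))
glance(cv)
#> # A tibble: 1 x 4
#>   model          k mean_accuracy sd_accuracy
#>   <chr>      <int>         <dbl>       <dbl>
#> 1 svm bp+csp    10             1           0
```

One hundred twenty two-second epochs, 60 per class; the default synthetic
contrast (a 3:1 alpha-power ratio between the classes, beta reversed) is
strong enough that all ten folds classify perfectly. `tidy(cv)` gives the
per-fold accuracies and AUCs. The convolutional route is one call away —
`run_cv(es, split_spec("kfold"), cnn_model())` — and a full
simulate-to-report run with manifests, training logs and a baseline table
is `run_pipeline(read_run_config(), "runs/demo")`. A thin CLI wrapper
(`inst/cli/sleepyeeg`) exposes `simulate`, `pipeline`, `cv` and `report`
subcommands.

The methods vignette (`vignettes/drowsiness-eeg-methods.Rmd`) documents
the signal model, every tunable default, and what passing tests do and do
not demonstrate about real recordings.

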