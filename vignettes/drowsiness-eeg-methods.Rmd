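---
title: "Methods: simulating and classifying drowsiness EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying drowsiness EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepyEEG)
```

## The problem

Drowsiness changes the spectral composition of scalp EEG in a well-known
way: alpha-band activity (8–13 Hz) grows as a person relaxes toward sleep,
while beta-band activity (13–30 Hz) dominates in an alert, decision-making
state. sleepyEEG implements a complete pipeline for exploiting that
contrast in a binary sleepy-vs-normal classifier: simulation of labeled
multichannel recordings, band-pass preprocessing and epoching,
multiplicative-noise data augmentation, classical band-power/CSP baselines,
a compact 1-D convolutional network, and an evaluation harness.

Because EEG recordings of sleep-deprived drivers are rarely shareable, the
package ships a generative model of the acquisition rather than data. Every
claim the test suite makes is therefore a claim about *recoverability*:
when data are generated with a known class contrast, the pipeline should
find it; when labels are shuffled, it should find nothing.

## The signal model

Scalp signals follow the instantaneous linear mixing model

$$X = A S + N,$$

where the rows of $S$ are latent sources, $A$ is an unknown channel ×
source mixing matrix and $N$ is i.i.d. Gaussian sensor noise. Each source
is simulated as a sum of narrow-band stochastic oscillations — white noise
band-passed to the delta, theta, alpha and beta bands and rescaled to a
target RMS amplitude — plus a $1/f$ pink-noise background. Narrow-band
filtered noise is the standard EEG surrogate: it has the right spectrum
and random phase without committing to any particular neural oscillator
model.

Class physiology enters only through the band amplitudes. The defaults
encode a 3:1 alpha-power contrast (sleepy 15 µV RMS alpha vs. normal
$15/\sqrt{3}$ µV) with beta dominance reversed (5 vs. 12 µV), identical
delta/theta activity (3 and 4 µV), a 2 µV background, and 1 µV sensor
noise. These amplitudes sit in the range a practitioner would call typical
for relaxed-adult scalp EEG, and the 3:1 alpha ratio is the contrast the
recovery experiments are built around. The measured channel-level alpha
ratio comes out slightly below 3 because mixing leakage and sensor noise
dilute the source contrast.

The default mixing matrix is the identity plus Gaussian off-diagonal
leakage (sd 0.1): every channel mostly sees "its" source with mild
cross-talk, a deliberately minimal stand-in for volume conduction. No
biophysical head model, eye-blink or EMG artifact simulation is attempted;
consequently the passing test suite shows the pipeline recovers *spectral*
class structure under mixing and noise, not that it is robust to real
recording artifacts.

The acquisition protocol mirrors a two-group sleep-deprivation study: 20
subjects, half sleep-deprived, three sessions of 7 minutes each (21
minutes per volunteer), nominally 40 trials per session, sampled at 500 Hz
on 8 channels. The "trials" are realized downstream by windowing the
continuous signal, not simulated as separate events. Each subject draws
one multiplicative gain (sd 0.05) applied to all of its sessions, so
between-subject amplitude variability persists across sessions and
subject-grouped splitting remains meaningful.

## Preprocessing

Recordings are band-passed to 1–30 Hz with a zero-phase Butterworth
filter. The filter order default is 5: applied forward–backward the
response is flat to within 0.01 dB at 10 Hz while 50 Hz mains is
attenuated by ≈ 49 dB. A 4th-order zero-phase design measures ≈ 39 dB at
50 Hz — just short of the 40 dB a clean mains-rejection criterion asks
for — which is why 5 is the default; both order and phase behaviour remain
user-settable in `filter_spec()`.

Continuous recordings are cut into fixed windows (default 2 s, no
overlap; both configurable). Two seconds at 500 Hz gives 210 epochs per
7-minute session — close to the nominal trial granularity while giving the
network enough training examples. Windows are half-open sample intervals
`[start, start + w)`; trailing samples that do not fill a window are
dropped. Epochs are zero-centered per channel, and an optional
peak-amplitude artifact gate (default 100 µV) discards epochs exceeding
the limit — a deliberately simple stand-in for "only clean trials are
kept"; no ICA or regression correction is attempted.

## Augmentation

Geometric transforms (flips, rotations, time-shifts) that enlarge image
datasets destroy the temporal structure EEG features live in. The
augmentation here instead multiplies an epoch elementwise by Gaussian
noise centered on 1:

$$x'_t = x_t \cdot n_t, \qquad n_t \sim \mathcal{N}(\mu, \sigma^2),$$

with $\mu = 1$ so the expected augmented epoch equals the original, and
$\sigma = 0.1$ as a mild default (the Monte-Carlo tests verify the
expectation property to 1% over 10,000 draws). The noise is drawn per
sample by default; a per-channel mode draws one factor per channel, which
scales each channel's spectrum uniformly and therefore preserves the
normalized PSD exactly. Whether the noise should multiply raw epochs or
extracted features is genuinely ambiguous in the drowsiness literature; the
package multiplies raw epochs, upstream of every feature extractor, so the
classical and deep pipelines benefit identically. Augmentation is applied
by the harness strictly after splitting and only to training partitions;
augmented epochs carry their source epoch's id so leakage is checkable (and
checked).

## Classical features

**Band power.** Welch's method (1 s Hann-windowed, mean-detrended
segments, 50% overlap) integrated over delta 1–4, theta 4–8, alpha 8–13
and beta 13–30 Hz — edges chosen to tile the 1–30 Hz passband. The PSD is
scaled so its integral equals the channel variance; unit tests pin the
sinusoid ($A^2/2$) and white-noise (variance) identities. Features are
log-transformed by default for the linear classifiers.

**CSP.** Standard two-class common spatial patterns: per-epoch covariances
are trace-normalized (so high-amplitude epochs do not dominate), averaged
per class, and the generalized eigenproblem
$C_A w = \lambda (C_A + C_B) w$ is solved by whitening $C_A + C_B$ and
diagonalizing the whitened $C_A$. Eigenvalues lie in $[0,1]$ and pair to 1
across classes; the default keeps 2 + 2 filters from the two tails. The
composite covariance is ridge-shrunk toward a scaled identity
(default weight $10^{-6}$) to keep the solve well-posed. Features are the
log of each filtered component's variance normalized by the total across
components. The implementation is verified against a brute-force
generalized eigendecomposition (`solve` + `eigen`) on 2- and 4-channel
problems to $10^{-8}$.

Baselines follow common practice: unpruned CART tree, LDA, RBF-kernel SVM
and 5-NN, each run on band power, CSP, and their concatenation under
identical splits. LDA is the plain MASS implementation (no shrinkage
variant is available in the dependency set); with tens of features and
hundreds of epochs per fold that is unproblematic.

## The compact convolutional network

The primary classifier is a small 1-D CNN operating on raw (filtered,
zero-centered) epochs of shape channels × samples. Three convolution
layers with kernel extents 5, 3 and 3 run along time with full channel
depth, each followed by ReLU; max-pooling (extent 4) follows the first
and second convolutions; two fully-connected layers (32 hidden units)
end in a softmax over the two classes. The first convolution uses
stride 4, decimating the 500 Hz input early — small kernels at full
temporal resolution cannot resolve 10 Hz vs. 20 Hz directly, but the
stride-and-pool cascade turns the stack into rectified band-energy
detectors with ~100 ms receptive fields, which is exactly the scale of the
alpha/beta contrast. A deeper transfer-style variant (96@11-stride-4
convolutions, cross-channel normalization, 3-wide stride-2 pooling,
4096-unit FC layers) is provided for freeze-and-fine-tune experiments; the
compact net is the recommended model.

Training is mini-batch SGD with momentum 0.9, batch size 32 and initial
learning rate 0.001 — deliberately conservative for small training sets —
minimizing softmax cross-entropy, with inputs standardized by the training
set's global mean and SD (stored with the model). After every epoch the
validation set is scored and a log row (epoch, iteration, elapsed time,
validation accuracy %, validation loss, learning rate) is appended;
training stops early after 5 epochs without validation-loss improvement
and the best-validation-loss weights are returned. Fine-tuning freezes a
layer prefix; frozen parameters are bit-identical before and after
training, which the test suite asserts literally.

The engine is written in vectorized base R: convolutions are a single
BLAS matrix product over a precomputed im2col gather, pooling and
normalization are array primitives, and the backward pass is verified
against central finite differences at $10^{-4}$ relative tolerance.
Training is deterministic given the configuration seed on single-threaded
BLAS.

## Evaluation

The holdout splitter stratifies by class (20% held out by default) and
can keep whole subjects on one side. k-fold CV (k = 10, shuffled)
deals each class's shuffled epochs round-robin into folds, so fold sizes
differ by at most one and per-fold class proportions stay within one epoch
of global — a stratified refinement of plain shuffled k-fold that keeps
every fold trainable. For the network, the held-out 20% is divided evenly
into a validation half (early stopping) and a test half (reported), since
a single "test and validation" pool would let the stopping rule peek at
the test data.

Metrics are computed from the thresholded scores (default threshold 0.5,
configurable): accuracy, per-class precision/recall/F1 (the positive
class swapped for the second row), the full ROC over unique score
thresholds and its trapezoid AUC. An undefined precision (no positive
predictions) is reported as 0 with an explicit flag rather than NaN.

## Problem sizes and what the tests show

The recovery experiments run on 2,000 two-second epochs from 20
single-session subjects (200 s each) at the default 3:1 alpha contrast:
10-fold CV of the RBF-SVM on band-power + CSP features and of the compact
CNN (≤ 15 training epochs per fold) must both reach mean accuracy ≥ 0.90,
and a label-shuffled control must stay within 0.50 ± 0.07. These sizes
give each fold ~1,800 training epochs, enough for the SGD schedule to
converge reliably; substantially smaller training sets leave the network
in its slow early phase. Passing shows the pipeline recovers a known
spectral contrast through mixing, noise, filtering and windowing — it does
not certify performance on real recordings, where artifacts,
non-stationarity and weaker, subject-variable contrasts dominate.

Numerical conventions worth knowing: Welch uses 1 s segments (frequency
resolution 1 Hz), bands are half-open `[low, high)`, CSP breaks ties by
eigenvalue order with first-hit argmax in pooling, and all seeds below
$2^{31}$ derive from a single user seed via one auxiliary RNG draw, so
every artifact of a run is reproducible from its manifest.

## Known limitations

* No artifact model (blinks, EMG, electrode pops); the artifact gate is a
  pure amplitude threshold.
* The mixing matrix is a minimal identity-plus-leakage surrogate, not a
  forward head model.
* The transfer-style variant is provided at blueprint fidelity but is far
  larger than the synthetic task warrants; training it at full width is
  not part of the test suite.
* LDA is unshrunk; with very short epochs or few epochs per class the
  band-power features can degenerate (constant columns) and LDA will
  refuse — use longer windows or the SVM in that regime.
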