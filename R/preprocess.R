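#' Band-pass filter specification
#'
#' Defaults follow the standard drowsiness-EEG passband of 1-30 Hz with a
#' zero-phase Butterworth design. The default order is 5: applied
#' forward-backward this yields a flat passband (gain within 1 dB at
#' 10 Hz) while attenuating 50 Hz mains by more than 40 dB at a 500 Hz
#' sampling rate; a 4th-order zero-phase design falls just short of 40 dB
#' there.
#'
#' @param low_cut,high_cut Band edges in Hz, `0 < low_cut < high_cut`.
#' @param order Butterworth order of a single pass.
#' @param zero_phase Apply forward-backward ([signal::filtfilt()]) so the
#'   filter has no group delay; otherwise a single causal pass.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_cut = 1, high_cut = 30, order = 5,
                        zero_phase = TRUE) {
  assert_scalar_number(low_cut, "low_cut", positive = TRUE)
  assert_scalar_number(high_cut, "high_cut", positive = TRUE)
  order <- assert_count(order, "order")
  if (low_cut >= high_cut) abort_bad_arg("`low_cut` must be below `high_cut`.")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth band-pass of `spec` to every channel. With
#' `zero_phase = TRUE` the filter runs forward and backward, doubling the
#' attenuation and cancelling the group delay.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()]. Cutoffs must lie below the Nyquist
#'   frequency of the recording.
#' @return The filtered recording (same shape and metadata).
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$sampling_rate / 2
  if (spec$high_cut >= nyq) {
    abort_bad_arg(sprintf(
      "high_cut (%g Hz) must be below the Nyquist frequency (%g Hz).",
      spec$high_cut, nyq))
  }
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- if (spec$zero_phase) {
      signal::filtfilt(bf, rec$data[ch, ])
    } else {
      as.numeric(signal::filter(bf, rec$data[ch, ]))
    }
  }
  rec$data <- out
  rec
}

#' @describeIn bandpass_filter Filter every recording of an `eeg_dataset`.
#' @param dataset An `eeg_dataset` from [generate_dataset()].
#' @export
bandpass_dataset <- function(dataset, spec = filter_spec()) {
  dataset$recording <- lapply(dataset$recording, bandpass_filter, spec = spec)
  dataset
}

#' Cut a recording into fixed-length epochs
#'
#' Slides a `window`-second window over the recording with step
#' `window * (1 - overlap_fraction)` and cuts every complete window;
#' trailing samples that do not fill a window are dropped. Windows are
#' half-open sample ranges `[start, start + w)`. Every epoch inherits the
#' recording's label and provenance.
#'
#' @param rec An [eeg_recording()].
#' @param window Window length in seconds; must not exceed the recording.
#' @param overlap_fraction Fraction of the window shared by consecutive
#'   epochs, in `[0, 1)`.
#' @return An [new_epoch_set()] with
#'   `floor((n_samples - w) / step) + 1` epochs.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), 500, label = "normal")
#' nrow(segment_recording(rec, window = 2))  # 5 epochs
#' @export
segment_recording <- function(rec, window = 2, overlap_fraction = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(window, "window", positive = TRUE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort_bad_arg("`overlap_fraction` must be in [0, 1).")
  }
  n <- ncol(rec$data)
  w <- round(window * rec$sampling_rate)
  if (w > n) abort_bad_arg("`window` is longer than the recording.")
  step <- max(1L, round(w * (1 - overlap_fraction)))
  n_epochs <- (n - w) %/% step + 1L
  starts <- (seq_len(n_epochs) - 1L) * step
  sig <- lapply(starts, function(s) rec$data[, (s + 1L):(s + w), drop = FALSE])
  new_epoch_set(
    tibble::tibble(
      subject_id = rec$subject_id,
      session_id = rec$session_id,
      label = rec$label,
      start_offset = starts / rec$sampling_rate,
      signal = sig
    ),
    sampling_rate = rec$sampling_rate, window = window
  )
}

#' @describeIn segment_recording Segment every recording of an
#'   `eeg_dataset` and pool the epochs into one `epoch_set`.
#' @param dataset An `eeg_dataset`.
#' @export
segment_dataset <- function(dataset, window = 2, overlap_fraction = 0) {
  parts <- lapply(dataset$recording, segment_recording,
                  window = window, overlap_fraction = overlap_fraction)
  df <- dplyr::bind_rows(lapply(parts, function(p) {
    p$epoch_id <- NULL; p$source_id <- NULL
    tibble::as_tibble(p)
  }))
  new_epoch_set(df, sampling_rate = parts[[1]] |> epoch_sampling_rate(),
                window = window)
}

#' Remove the per-channel mean of every epoch
#'
#' Zero-center normalization: each channel of each epoch has its mean
#' subtracted, so every output channel averages to zero. Idempotent.
#'
#' @param es An `epoch_set`.
#' @return The zero-centered `epoch_set`.
#' @export
zero_center_epochs <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  es$signal <- lapply(es$signal, function(m) m - rowMeans(m))
  es
}

#' Reject high-amplitude artifact epochs
#'
#' Keeps epochs whose peak absolute amplitude does not exceed
#' `amplitude_limit`, preserving order. Intended to emulate discarding
#' noisy trials before augmentation or training.
#'
#' @param es An `epoch_set`.
#' @param amplitude_limit Peak |amplitude| threshold in microvolts (> 0).
#' @return The surviving subsequence of `es`; warns if nothing survives.
#' @export
reject_artifacts <- function(es, amplitude_limit = 100) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.numeric(amplitude_limit) || length(amplitude_limit) != 1L ||
      is.na(amplitude_limit) || amplitude_limit <= 0) {
    abort_bad_arg("`amplitude_limit` must be a single value > 0 (Inf allowed).")
  }
  keep <- vapply(es$signal, function(m) max(abs(m)) <= amplitude_limit,
                 logical(1))
  out <- restore_epoch_set(es[keep, , drop = FALSE], es)
  if (nrow(out) == 0 && nrow(es) > 0) {
    rlang::warn("All epochs exceeded the amplitude limit; returning an empty epoch_set.")
  }
  out
}
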