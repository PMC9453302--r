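#' Construct an EEG recording object
#'
#' A recording is one continuous multichannel signal (channels x samples,
#' microvolts) with its sampling rate, provenance identifiers and class
#' label attached.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate, Hz.
#' @param subject_id,session_id Provenance identifiers.
#' @param label `"sleepy"` or `"normal"`.
#' @param channel_names Optional channel names; default `ch1..chN`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sampling_rate, subject_id = "s01",
                          session_id = "r01", label = c("sleepy", "normal"),
                          channel_names = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) abort_bad_arg("Recording values must be finite.")
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  label <- match.arg(label)
  channel_names <- channel_names %||% paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) {
    abort_bad_arg("`channel_names` length must equal the channel count.")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, sampling_rate = sampling_rate,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         label = label, channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s [%s] %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_id, x$label, nrow(x$data),
              ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

# unit-RMS narrow-band noise via zero-phase Butterworth filtering of white
# noise; pad samples on each side absorb the filter transient
narrowband_noise <- function(n, low, high, rate) {
  nyq <- rate / 2
  low <- max(low, 1e-3)
  high <- min(high, nyq * 0.99)
  pad <- min(n, 2L * as.integer(rate))
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# unit-RMS 1/f^exponent background noise by FFT spectral shaping
background_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  f <- stats::fft(w)
  freqs <- c(1, seq_len(n - 1))              # avoid the DC singularity
  shape <- freqs^(-exponent / 2)
  shape[1] <- 0                              # remove DC entirely
  # enforce conjugate symmetry by shaping symmetric frequencies equally
  k <- seq_len(n %/% 2)
  shape[n + 1 - k] <- shape[k + 1]
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate latent EEG sources
#'
#' Each of the `n_sources` rows is an independent realization of the source
#' spectrum: a sum of band-limited stochastic oscillations with random
#' phase (narrow-band filtered white noise, scaled to the band's RMS
#' amplitude) plus a 1/f-type broadband background. Deterministic given
#' `seed`.
#'
#' @param spec A [source_spec()].
#' @param duration Length in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0).
#' @param n_sources Number of independent source rows.
#' @param seed Integer seed.
#' @return Matrix `n_sources` x `round(duration * rate)`, microvolts.
#' @export
generate_sources <- function(spec, duration, rate, n_sources = 8, seed = 1L) {
  stopifnot(inherits(spec, "source_spec"))
  assert_scalar_number(duration, "duration", positive = TRUE)
  assert_scalar_number(rate, "rate", positive = TRUE)
  n_sources <- assert_count(n_sources, "n_sources")
  n <- round(duration * rate)
  withr::with_seed(as.integer(seed), {
    S <- matrix(0, n_sources, n)
    for (s in seq_len(n_sources)) {
      x <- numeric(n)
      for (b in seq_len(nrow(spec$bands))) {
        amp <- spec$bands$amplitude[b]
        if (amp <= 0) next
        lo <- spec$bands$center[b] - spec$bands$bandwidth[b] / 2
        hi <- spec$bands$center[b] + spec$bands$bandwidth[b] / 2
        x <- x + amp * narrowband_noise(n, lo, hi, rate)
      }
      if (spec$background_sd > 0) {
        x <- x + spec$background_sd * background_noise(n, spec$background_exponent)
      }
      S[s, ] <- x
    }
    S
  })
}

#' Mix sources onto channels under the linear forward model
#'
#' Applies `X = A S + N`: the mixing matrix projects sources onto channels
#' and i.i.d. zero-mean Gaussian sensor noise of the model's standard
#' deviation is added. Deterministic given `seed`.
#'
#' @param S Source matrix (sources x samples), e.g. [generate_sources()].
#' @param model A [mixing_model()]; column count of `A` must equal
#'   `nrow(S)`.
#' @param seed Integer seed for the sensor-noise draw.
#' @return Channel matrix (channels x samples).
#' @export
mix_sources <- function(S, model, seed = 1L) {
  stopifnot(inherits(model, "mixing_model"))
  S <- as.matrix(S)
  if (ncol(model$A) != nrow(S)) {
    abort_bad_arg(sprintf(
      "Dimension mismatch: mixing matrix has %d source columns but S has %d source rows.",
      ncol(model$A), nrow(S)))
  }
  X <- model$A %*% S
  if (model$sensor_noise_sd > 0) {
    N <- withr::with_seed(as.integer(seed),
      matrix(stats::rnorm(length(X), 0, model$sensor_noise_sd),
             nrow(X), ncol(X)))
    X <- X + N
  }
  X
}

#' Generate a labeled synthetic EEG dataset
#'
#' Produces one recording per subject and session under the acquisition
#' protocol. Each subject draws a single multiplicative gain (mean 1, sd
#' `per_subject_gain_sd`) applied to its sources, so between-subject
#' amplitude variability is preserved across sessions. Labels follow the
#' protocol's group assignment: deprived subjects yield `"sleepy"`
#' recordings, normal sleepers `"normal"` ones. Fully reproducible given
#' `seed`.
#'
#' @param protocol A [session_protocol()].
#' @param sleepy_spec,normal_spec [source_spec()]s for the two groups.
#' @param model A [mixing_model()]; default identity-plus-leakage for the
#'   protocol's channel count.
#' @param seed Integer master seed.
#' @return An `eeg_dataset`: a tibble with one row per recording
#'   (`subject_id`, `session_id`, `label`, `recording` list-column) and the
#'   protocol and seed stored as attributes.
#' @export
generate_dataset <- function(protocol = make_default_protocol(),
                             sleepy_spec = sleepy_source_spec(),
                             normal_spec = normal_source_spec(),
                             model = NULL,
                             seed = 1L) {
  stopifnot(inherits(protocol, "session_protocol"),
            inherits(sleepy_spec, "source_spec"),
            inherits(normal_spec, "source_spec"))
  model <- model %||% default_mixing_model(
    n_channels = protocol$n_channels, seed = seed)
  n_rec <- protocol$n_subjects * protocol$n_sessions_per_subject
  seeds <- derive_seeds(seed, 2L * n_rec + protocol$n_subjects)
  gain_seed <- seeds[2L * n_rec + 1L]
  gains <- withr::with_seed(gain_seed, {
    g <- stats::rnorm(protocol$n_subjects, 1,
                      max(sleepy_spec$per_subject_gain_sd,
                          normal_spec$per_subject_gain_sd))
    pmax(g, 0.1)
  })
  rows <- vector("list", n_rec)
  k <- 0L
  for (i in seq_len(protocol$n_subjects)) {
    grp <- protocol$group_assignment[i]
    spec <- if (grp == "deprived") sleepy_spec else normal_spec
    label <- if (grp == "deprived") "sleepy" else "normal"
    sid <- sprintf("s%02d", i)
    for (j in seq_len(protocol$n_sessions_per_subject)) {
      k <- k + 1L
      S <- generate_sources(spec, protocol$session_duration,
                            protocol$sampling_rate,
                            n_sources = ncol(model$A),
                            seed = seeds[2L * k - 1L])
      X <- mix_sources(gains[i] * S, model, seed = seeds[2L * k])
      rows[[k]] <- tibble::tibble(
        subject_id = sid,
        session_id = sprintf("r%02d", j),
        label = label,
        recording = list(eeg_recording(
          X, protocol$sampling_rate, subject_id = sid,
          session_id = sprintf("r%02d", j), label = label))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("eeg_dataset", class(out))
  out
}
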