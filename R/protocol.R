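#' Acquisition protocol for a simulated drowsiness study
#'
#' Describes the recording session layout the synthetic generator emulates:
#' how many subjects, how many sessions each, how long a session lasts,
#' nominal trials per session, the sampling rate and the channel count, and
#' which group (normal sleep vs. sleep deprived) each subject belongs to.
#' Sleep-deprived subjects' recordings carry the `"sleepy"` label, normal
#' sleepers the `"normal"` label.
#'
#' @param n_subjects Number of volunteers.
#' @param n_sessions_per_subject Recording sessions per volunteer.
#' @param session_duration Duration of one continuous session, seconds.
#' @param n_trials_per_session Nominal trial count per session. Trials are
#'   realized downstream by [segment_recording()], not simulated as separate
#'   events.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_channels Number of EEG channels.
#' @param group_assignment Character vector of length `n_subjects` with
#'   values `"normal"` or `"deprived"`. Default: the first half of the
#'   subjects is assigned to the deprived group, the rest to the normal
#'   group.
#'
#' @return A `session_protocol` object (a list).
#' @examples
#' p <- make_default_protocol()
#' p$n_subjects * p$n_sessions_per_subject # 60 recordings
#' @export
session_protocol <- function(n_subjects = 20,
                             n_sessions_per_subject = 3,
                             session_duration = 420,
                             n_trials_per_session = 40,
                             sampling_rate = 500,
                             n_channels = 8,
                             group_assignment = NULL) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_sessions_per_subject <- assert_count(n_sessions_per_subject, "n_sessions_per_subject")
  n_trials_per_session <- assert_count(n_trials_per_session, "n_trials_per_session")
  n_channels <- assert_count(n_channels, "n_channels")
  assert_scalar_number(session_duration, "session_duration", positive = TRUE)
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(group_assignment)) {
    n_dep <- ceiling(n_subjects / 2)
    group_assignment <- c(rep("deprived", n_dep), rep("normal", n_subjects - n_dep))
  }
  group_assignment <- as.character(group_assignment)
  if (length(group_assignment) != n_subjects ||
      !all(group_assignment %in% c("normal", "deprived"))) {
    abort_bad_arg(
      "`group_assignment` must give 'normal' or 'deprived' for every subject.")
  }
  structure(
    list(
      n_subjects = n_subjects,
      n_sessions_per_subject = n_sessions_per_subject,
      session_duration = session_duration,
      n_trials_per_session = n_trials_per_session,
      sampling_rate = sampling_rate,
      n_channels = n_channels,
      group_assignment = group_assignment
    ),
    class = "session_protocol"
  )
}

#' @describeIn session_protocol The study default: 20 subjects in two
#'   groups, 3 sessions of 7 minutes each (21 minutes per volunteer), 40
#'   nominal trials per session, 500 Hz, 8 channels.
#' @export
make_default_protocol <- function() session_protocol()

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf(
    "<session_protocol> %d subjects x %d sessions, %g s @ %g Hz, %d channels\n",
    x$n_subjects, x$n_sessions_per_subject, x$session_duration,
    x$sampling_rate, x$n_channels))
  cat(sprintf("  groups: %d deprived / %d normal; %d nominal trials/session\n",
              sum(x$group_assignment == "deprived"),
              sum(x$group_assignment == "normal"),
              x$n_trials_per_session))
  invisible(x)
}

#' Spectral specification of a latent EEG source class
#'
#' A source is simulated as a sum of narrow-band stochastic oscillations
#' (one per row of `bands`) plus a 1/f^`background_exponent` background.
#' Amplitudes are the RMS contribution of each band component in microvolts.
#' A drowsy ("sleepy") source must have more alpha (8-13 Hz) than beta
#' (13-30 Hz) power; an alert ("normal") source the reverse.
#'
#' @param class_label `"sleepy"` or `"normal"`.
#' @param bands Data frame with columns `name`, `amplitude` (RMS uV),
#'   `center` (Hz) and `bandwidth` (Hz). The band covers
#'   `center +/- bandwidth/2`.
#' @param background_exponent Spectral slope of the broadband background
#'   (power ~ 1/f^exponent). 1 is the usual pink-noise EEG floor.
#' @param background_sd RMS amplitude (uV) of the background component.
#' @param per_subject_gain_sd Standard deviation of the multiplicative
#'   per-subject gain (mean 1) applied by [generate_dataset()].
#'
#' @return A `source_spec` object.
#' @seealso [sleepy_source_spec()], [normal_source_spec()]
#' @export
source_spec <- function(class_label,
                        bands,
                        background_exponent = 1,
                        background_sd = 2,
                        per_subject_gain_sd = 0.05) {
  class_label <- match.arg(class_label, c("sleepy", "normal"))
  bands <- tibble::as_tibble(bands)
  needed <- c("name", "amplitude", "center", "bandwidth")
  if (!all(needed %in% names(bands))) {
    abort_bad_arg("`bands` needs columns name, amplitude, center, bandwidth.")
  }
  if (any(bands$amplitude < 0)) abort_bad_arg("Band amplitudes must be >= 0.")
  assert_scalar_number(background_exponent, "background_exponent", nonneg = TRUE)
  assert_scalar_number(background_sd, "background_sd", nonneg = TRUE)
  assert_scalar_number(per_subject_gain_sd, "per_subject_gain_sd", nonneg = TRUE)
  spec <- structure(
    list(class_label = class_label, bands = bands,
         background_exponent = background_exponent,
         background_sd = background_sd,
         per_subject_gain_sd = per_subject_gain_sd),
    class = "source_spec"
  )
  pow <- band_rms(spec)
  if (class_label == "sleepy" && !(pow["alpha"] > pow["beta"])) {
    abort_bad_arg("A sleepy source_spec needs alpha amplitude > beta amplitude.")
  }
  if (class_label == "normal" && !(pow["beta"] > pow["alpha"])) {
    abort_bad_arg("A normal source_spec needs beta amplitude > alpha amplitude.")
  }
  spec
}

band_rms <- function(spec) {
  out <- c(alpha = 0, beta = 0)
  for (nm in names(out)) {
    i <- match(nm, spec$bands$name)
    if (!is.na(i)) out[nm] <- spec$bands$amplitude[i]
  }
  out
}

#' @describeIn source_spec Convenience band table (delta/theta/alpha/beta
#'   rows at the canonical centers) with configurable RMS amplitudes.
#' @param alpha,beta,delta,theta RMS amplitudes (uV) per band.
#' @export
default_band_table <- function(alpha, beta, delta = 3, theta = 4) {
  tibble::tibble(
    name      = c("delta", "theta", "alpha", "beta"),
    amplitude = c(delta, theta, alpha, beta),
    center    = c(2.5, 6, 10.5, 21.5),
    bandwidth = c(3, 4, 5, 17)
  )
}

#' Default drowsy and alert source spectra
#'
#' The defaults encode a 3:1 alpha-band power contrast between the sleepy
#' and normal classes (RMS amplitudes 15 uV vs. 15/sqrt(3) uV, a power
#' ratio of exactly 3), with beta dominance reversed (5 uV vs. 12 uV), on
#' top of identical delta/theta activity and a pink-noise background.
#'
#' @param alpha,beta RMS amplitudes (uV) of the alpha and beta components.
#' @return A `source_spec`.
#' @export
sleepy_source_spec <- function(alpha = 15, beta = 5) {
  source_spec("sleepy", default_band_table(alpha = alpha, beta = beta))
}

#' @rdname sleepy_source_spec
#' @export
normal_source_spec <- function(alpha = 15 / sqrt(3), beta = 12) {
  source_spec("normal", default_band_table(alpha = alpha, beta = beta))
}

#' Linear sensor mixing model
#'
#' The forward model for the simulated scalp signal, `X = A S + N`: sources
#' `S` are projected onto the channels through the mixing matrix `A` and
#' i.i.d. Gaussian sensor noise `N` is added.
#'
#' @param A Mixing matrix, channels x sources. Every channel must see at
#'   least one source (no all-zero row).
#' @param sensor_noise_sd Standard deviation (uV) of the additive sensor
#'   noise.
#' @return A `mixing_model` object.
#' @export
mixing_model <- function(A, sensor_noise_sd = 1) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) abort_bad_arg("Mixing matrix must be finite.")
  if (any(rowSums(abs(A)) == 0)) {
    abort_bad_arg("Mixing matrix has an all-zero row: every channel must see some source.")
  }
  assert_scalar_number(sensor_noise_sd, "sensor_noise_sd", nonneg = TRUE)
  structure(list(A = A, sensor_noise_sd = sensor_noise_sd),
            class = "mixing_model")
}

#' @describeIn mixing_model Identity mixing plus small random off-diagonal
#'   leakage (sd `leakage_sd`), the package default when no head model is
#'   given.
#' @param n_channels,n_sources Dimensions of the default matrix.
#' @param leakage_sd Standard deviation of the off-diagonal leakage terms.
#' @param seed Integer seed controlling the leakage draw.
#' @export
default_mixing_model <- function(n_channels = 8, n_sources = n_channels,
                                 leakage_sd = 0.1, sensor_noise_sd = 1,
                                 seed = 1L) {
  A <- withr::with_seed(as.integer(seed), {
    m <- matrix(stats::rnorm(n_channels * n_sources, 0, leakage_sd),
                n_channels, n_sources)
    for (i in seq_len(min(n_channels, n_sources))) m[i, i] <- 0
    m + diag(1, n_channels, n_sources)
  })
  mixing_model(A, sensor_noise_sd = sensor_noise_sd)
}
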