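#' Canonical EEG frequency bands
#'
#' Band edges tiling the 1-30 Hz analysis passband: delta 1-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz. A band covers the half-open interval
#' `[low, high)`.
#'
#' @return Tibble with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  tibble::tibble(
    name = c("delta", "theta", "alpha", "beta"),
    low  = c(1, 4, 8, 13),
    high = c(4, 8, 13, 30)
  )
}

# Welch PSD of a channels x samples matrix.  Hann window, mean-detrended
# segments, one-sided density scaled so that sum(psd) * df equals the
# signal variance (Parseval).  Returns list(freq, psd[ch, freq]).
welch_psd_matrix <- function(m, rate, segment_length = NULL, overlap = 0.5) {
  n <- ncol(m)
  nper <- as.integer(segment_length %||% min(n, round(rate)))
  if (nper > n) abort_bad_arg("`segment_length` exceeds the epoch length.")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- 1 / (rate * sum(w^2))
  nf <- nper %/% 2L + 1L
  acc <- matrix(0, nrow(m), nf)
  for (s in starts) {
    seg <- m[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, `*`)
    ft <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]
    p <- (Mod(ft)^2) * scale
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nper %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + t(p * dbl)
  }
  list(freq = (seq_len(nf) - 1L) * rate / nper, psd = acc / length(starts))
}

#' Welch power spectral density of an epoch
#'
#' Averaged modified periodograms (Hann window, mean-detrended segments,
#' 50% overlap by default). The density is one-sided and scaled so that
#' its integral over frequency equals the channel variance.
#'
#' @param e A one-row `epoch_set`, an [eeg_recording()], or a channels x
#'   samples matrix.
#' @param rate Sampling rate in Hz (taken from the object when available).
#' @param segment_length Segment length in samples; default one second of
#'   signal (or the whole epoch if shorter).
#' @param overlap Segment overlap fraction.
#' @return A tibble with columns `channel`, `frequency` and `density`
#'   (power per Hz), of class `welch_psd`.
#' @export
welch_psd <- function(e, rate = NULL, segment_length = NULL, overlap = 0.5) {
  if (inherits(e, "epoch_set")) {
    stopifnot(nrow(e) == 1L)
    rate <- rate %||% epoch_sampling_rate(e)
    m <- e$signal[[1]]
  } else if (inherits(e, "eeg_recording")) {
    rate <- rate %||% e$sampling_rate
    m <- e$data
  } else {
    m <- as.matrix(e)
    if (is.null(rate)) abort_bad_arg("`rate` is required for a plain matrix.")
  }
  res <- welch_psd_matrix(m, rate, segment_length, overlap)
  ch <- rownames(m) %||% paste0("ch", seq_len(nrow(m)))
  out <- tibble::tibble(
    channel = rep(ch, each = length(res$freq)),
    frequency = rep(res$freq, nrow(m)),
    density = as.vector(t(res$psd))
  )
  class(out) <- c("welch_psd", class(out))
  out
}

# integrate a PSD matrix over [low, high) per channel
integrate_band <- function(freq, psd, low, high) {
  sel <- freq >= low & freq < high
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  rowSums(psd[, sel, drop = FALSE]) * df
}

#' Band power of an epoch
#'
#' Integrates the Welch PSD of each channel over each frequency band. A
#' unit-amplitude sinusoid inside a band contributes ~A^2/2 = 0.5 to that
#' band; scaling the signal by c scales every band power by c^2.
#'
#' @param e A one-row `epoch_set`, recording, or channels x samples matrix.
#' @param bands Band table as from [default_bands()]; all bands must lie
#'   below the Nyquist frequency.
#' @param rate Sampling rate in Hz (taken from the object when available).
#' @param log Return `log(power + eps)` instead of raw power.
#' @param segment_length Welch segment length (samples).
#' @return Named numeric vector of length `n_channels * n_bands` with
#'   names `<channel>_<band>`.
#' @export
band_power <- function(e, bands = default_bands(), rate = NULL, log = FALSE,
                       segment_length = NULL) {
  if (inherits(e, "epoch_set")) {
    stopifnot(nrow(e) == 1L)
    rate <- rate %||% epoch_sampling_rate(e)
    m <- e$signal[[1]]
  } else if (inherits(e, "eeg_recording")) {
    rate <- rate %||% e$sampling_rate
    m <- e$data
  } else {
    m <- as.matrix(e)
    if (is.null(rate)) abort_bad_arg("`rate` is required for a plain matrix.")
  }
  bands <- tibble::as_tibble(bands)
  if (any(bands$high > rate / 2)) {
    abort_bad_arg("A band extends beyond the Nyquist frequency.")
  }
  res <- welch_psd_matrix(m, rate, segment_length)
  ch <- rownames(m) %||% paste0("ch", seq_len(nrow(m)))
  out <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    p <- integrate_band(res$freq, res$psd, bands$low[b], bands$high[b])
    names(p) <- paste0(ch, "_", bands$name[b])
    out <- c(out, p)
  }
  if (log) out <- base::log(out + 1e-12)
  out
}

#' Band-power feature matrix for an epoch set
#'
#' Extracts [band_power()] features for every epoch. Log-transformed by
#' default, which symmetrizes the heavy-tailed power distribution for the
#' linear classifiers.
#'
#' @param es An `epoch_set`.
#' @param bands Band table, see [default_bands()].
#' @param log Log-transform the powers.
#' @param prefix Prefix for feature column names.
#' @return A `feature_matrix` tibble: one row per epoch, a `label` column
#'   plus one column per channel x band.
#' @export
bp_features <- function(es, bands = default_bands(), log = TRUE,
                        prefix = "bp") {
  stopifnot(inherits(es, "epoch_set"))
  rate <- epoch_sampling_rate(es)
  rows <- lapply(es$signal, band_power, bands = bands, rate = rate, log = log)
  vals <- do.call(rbind, rows)
  colnames(vals) <- paste0(prefix, "_", colnames(vals))
  new_feature_matrix(vals, es$label)
}
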