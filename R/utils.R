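# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg, class = "sleepyEEG_error") {
  rlang::abort(msg, class = c(class, "sleepyEEG_error"))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort_bad_arg(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort_bad_arg(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != as.integer(x)) {
    abort_bad_arg(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Deterministic sub-seed derivation: draws `n` integer seeds under `seed`
# without touching the caller's RNG state.  Keeps every derived seed below
# 2^31 so it is a valid R integer.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

hhmmss <- function(secs) {
  secs <- max(0, round(secs))
  sprintf("%02d:%02d:%02d", secs %/% 3600L, (secs %% 3600L) %/% 60L, secs %% 60L)
}
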