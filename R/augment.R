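#' Multiplicative-noise augmentation specification
#'
#' Training epochs are enlarged by elementwise multiplication with Gaussian
#' noise centered on 1, which preserves the temporal and spectral structure
#' of the EEG in expectation (E\[x * n\] = mu * x) - unlike geometric
#' transforms (flips, rotations, shifts), which destroy the time-series
#' features the classifier relies on.
#'
#' @param mu Mean of the multiplicative noise; 1 leaves the expected signal
#'   unchanged.
#' @param sigma Standard deviation of the noise (>= 0). The default 0.1 is
#'   a mild perturbation that preserves class structure.
#' @param copies_per_epoch Augmented copies generated per original epoch.
#' @param seed Integer seed controlling all draws.
#' @param mode `"per_sample"` draws one noise value per sample (a noise
#'   array the size of the epoch); `"per_channel"` draws a single value per
#'   channel, scaling each channel's amplitude uniformly.
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(mu = 1, sigma = 0.1, copies_per_epoch = 2,
                         seed = 1L, mode = c("per_sample", "per_channel")) {
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma, "sigma", nonneg = TRUE)
  copies_per_epoch <- assert_count(copies_per_epoch, "copies_per_epoch", min = 0L)
  mode <- match.arg(mode)
  structure(list(mu = mu, sigma = sigma, copies_per_epoch = copies_per_epoch,
                 seed = as.integer(seed), mode = mode),
            class = "augment_spec")
}

#' Gaussian probability density
#'
#' The density of a Gaussian random variable `z` with mean `mu` and
#' standard deviation `sigma`:
#' `P(z) = exp(-(z - mu)^2 / (2 sigma^2)) / (sigma sqrt(2 pi))`.
#' This is the distribution from which the multiplicative noise is drawn.
#'
#' @param z Quantile(s).
#' @param mu Mean.
#' @param sigma Standard deviation (> 0).
#' @return Density value(s).
#' @export
gaussian_pdf <- function(z, mu = 1, sigma = 0.1) {
  assert_scalar_number(sigma, "sigma", positive = TRUE)
  exp(-(z - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# matrix-level core shared by the epoch-level and set-level interfaces
multiply_noise <- function(m, spec, draw_seed) {
  if (spec$sigma == 0 && spec$mu == 1) return(m)
  withr::with_seed(as.integer(draw_seed), {
    noise <- if (spec$mode == "per_sample") {
      matrix(stats::rnorm(length(m), spec$mu, spec$sigma), nrow(m), ncol(m))
    } else {
      stats::rnorm(nrow(m), spec$mu, spec$sigma)
    }
    m * noise
  })
}

#' Augment a single epoch with multiplicative Gaussian noise
#'
#' Multiplies the epoch's signal by noise drawn from
#' `Normal(spec$mu, spec$sigma)` - per sample or per channel depending on
#' `spec$mode` - and flags the result as augmented. The label and
#' provenance are preserved so subject-aware splitting remains possible.
#'
#' @param e A one-row `epoch_set` (a single epoch).
#' @param spec An [augment_spec()].
#' @param draw_seed Integer seed for this draw; identical seeds give
#'   identical output.
#' @return A one-row `epoch_set` with `augmented = TRUE`.
#' @export
multiplicative_noise_epoch <- function(e, spec = augment_spec(), draw_seed = 1L) {
  stopifnot(inherits(e, "epoch_set"), nrow(e) == 1L,
            inherits(spec, "augment_spec"))
  e$signal[[1]] <- multiply_noise(e$signal[[1]], spec, draw_seed)
  e$augmented <- TRUE
  e
}

#' Enlarge an epoch set by multiplicative-noise augmentation
#'
#' Returns the original epochs followed by `copies_per_epoch` augmented
#' variants of each, so the output holds `n * (1 + copies_per_epoch)`
#' epochs and class proportions are unchanged. Augmented epochs keep their
#' source epoch's `source_id`, which the evaluation harness uses to ensure
#' no augmented copy of a test epoch ever reaches a training set.
#'
#' @param es An `epoch_set`.
#' @param spec An [augment_spec()]; all draws derive from `spec$seed`.
#' @return The augmented `epoch_set`.
#' @export
augment_epochset <- function(es, spec = augment_spec()) {
  stopifnot(inherits(es, "epoch_set"), inherits(spec, "augment_spec"))
  if (spec$copies_per_epoch == 0L || nrow(es) == 0L) return(es)
  n <- nrow(es)
  seeds <- derive_seeds(spec$seed, n * spec$copies_per_epoch)
  copies <- vector("list", spec$copies_per_epoch)
  next_id <- max(es$epoch_id)
  for (c_i in seq_len(spec$copies_per_epoch)) {
    cp <- tibble::as_tibble(es)
    cp$source_id <- es$epoch_id
    cp$epoch_id <- next_id + seq_len(n)
    next_id <- next_id + n
    cp$augmented <- TRUE
    cp$signal <- lapply(seq_len(n), function(i) {
      multiply_noise(es$signal[[i]], spec, seeds[(c_i - 1L) * n + i])
    })
    copies[[c_i]] <- cp
  }
  restore_epoch_set(dplyr::bind_rows(c(list(tibble::as_tibble(es)), copies)), es)
}
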