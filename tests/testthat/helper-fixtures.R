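# Fixtures are generated in code; nothing is read from disk.

`%||%` <- function(x, y) if (is.null(x)) y else x

# a single sinusoid epoch replicated over channels
sine_epoch_matrix <- function(freq, rate = 500, n = 1000, nch = 2, amp = 1,
                              phase = 0) {
  t <- (seq_len(n) - 1) / rate
  matrix(rep(amp * sin(2 * pi * freq * t + phase), each = nch), nch, n,
         byrow = FALSE)
}

# epoch_set built directly from a list of matrices
epochs_from_matrices <- function(mats, labels, rate = 500,
                                 subject_id = NULL) {
  w <- ncol(mats[[1]]) / rate
  new_epoch_set(
    tibble::tibble(
      subject_id = subject_id %||% rep("s01", length(mats)),
      session_id = "r01",
      label = labels,
      signal = mats
    ),
    sampling_rate = rate, window = w
  )
}

# fast separable two-class epochs: class A = 10 Hz + noise, class B = 22 Hz
# + noise, random phases; cheap stand-in for fully simulated recordings
toy_band_epochs <- function(n_per_class = 20, nch = 2, n = 500, rate = 500,
                            seed = 42) {
  withr::with_seed(seed, {
    mats <- c(
      lapply(seq_len(n_per_class), function(i) {
        sine_epoch_matrix(10, rate, n, nch, amp = 3,
                          phase = stats::runif(1, 0, 2 * pi)) +
          matrix(stats::rnorm(nch * n, 0, 0.5), nch, n)
      }),
      lapply(seq_len(n_per_class), function(i) {
        sine_epoch_matrix(22, rate, n, nch, amp = 3,
                          phase = stats::runif(1, 0, 2 * pi)) +
          matrix(stats::rnorm(nch * n, 0, 0.5), nch, n)
      })
    )
    epochs_from_matrices(
      mats, c(rep("sleepy", n_per_class), rep("normal", n_per_class)),
      rate = rate,
      subject_id = rep(sprintf("s%02d", rep(1:4, length.out = n_per_class)), 2))
  })
}

# two-channel toy where class A ("normal", first alphabetically) has
# variance only on channel 1 and class B ("sleepy") only on channel 2:
# the canonical CSP test problem
toy_csp_epochs <- function(n_per_class = 30, n = 200, eps = 1e-3, seed = 7) {
  withr::with_seed(seed, {
    mats <- c(
      lapply(seq_len(n_per_class), function(i) {
        rbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, eps))
      }),
      lapply(seq_len(n_per_class), function(i) {
        rbind(stats::rnorm(n, 0, eps), stats::rnorm(n, 0, 1))
      })
    )
    epochs_from_matrices(
      mats, c(rep("normal", n_per_class), rep("sleepy", n_per_class)),
      rate = 100)
  })
}

# small fully simulated dataset through the real generator
small_sim_epochs <- function(n_subjects = 4, duration = 20, seed = 11,
                             window = 2) {
  p <- session_protocol(n_subjects = n_subjects, n_sessions_per_subject = 1,
                        session_duration = duration)
  ds <- bandpass_dataset(generate_dataset(p, seed = seed))
  zero_center_epochs(segment_dataset(ds, window = window))
}

# independent generalized-eigenproblem oracle for CSP:
# solves C_a w = lambda (C_a + C_b) w by brute force via solve()
csp_oracle <- function(Ca, Cb) {
  M <- solve(Ca + Cb, Ca)
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# class-average trace-normalized covariance, as the CSP fit defines it
class_avg_cov <- function(es, lbl) {
  idx <- which(es$label == lbl)
  p <- nrow(es$signal[[1]])
  acc <- matrix(0, p, p)
  for (i in idx) {
    x <- es$signal[[i]]
    x <- x - rowMeans(x)
    cc <- tcrossprod(x)
    acc <- acc + cc / sum(diag(cc))
  }
  acc / length(idx)
}
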