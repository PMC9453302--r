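test_that("Welch PSD satisfies the power identities", {
  # zero signal -> zero density
  z <- welch_psd(matrix(0, 1, 1000), rate = 500)
  expect_true(all(z$density == 0))

  # unit-amplitude sinusoid: total power A^2/2 = 0.5
  m <- sine_epoch_matrix(10, 500, 2000, nch = 1)
  p <- welch_psd(m, rate = 500)
  df <- diff(p$frequency[1:2])
  expect_equal(sum(p$density) * df, 0.5, tolerance = 0.02)

  # white noise: integrated density ~ variance
  withr::with_seed(3, {
    w <- matrix(rnorm(4000), 1)
    pw <- welch_psd(w, rate = 500)
    expect_equal(sum(pw$density) * diff(pw$frequency[1:2]),
                 stats::var(as.vector(w)), tolerance = 0.05)
  })
  expect_error(welch_psd(matrix(0, 1, 100), rate = 500, segment_length = 500),
               "exceeds")
})

test_that("band power isolates a sinusoid's band and scales quadratically", {
  m <- sine_epoch_matrix(10, 500, 2000, nch = 1)
  bp <- band_power(m, rate = 500)
  expect_equal(bp[["ch1_alpha"]], 0.5, tolerance = 0.05)
  expect_lt(bp[["ch1_beta"]], 1e-3)
  expect_true(all(band_power(matrix(0, 2, 1000), rate = 500) == 0))

  bp3 <- band_power(3 * m, rate = 500)
  expect_equal(bp3[["ch1_alpha"]] / bp[["ch1_alpha"]], 9, tolerance = 1e-6)

  wide <- tibble::tibble(name = "hf", low = 100, high = 400)
  expect_error(band_power(m, bands = wide, rate = 500), "Nyquist")
})

test_that("band power agrees with time-domain variance of band-filtered noise", {
  # brute-force oracle: brick-wall FFT filter, then time-domain variance
  brickwall_var <- function(x, low, high, rate) {
    n <- length(x)
    f <- (seq_len(n) - 1) * rate / n
    f <- pmin(f, rate - f)                   # two-sided frequency axis
    ft <- stats::fft(x)
    ft[f < low | f >= high] <- 0
    stats::var(Re(stats::fft(ft, inverse = TRUE)) / n)
  }
  withr::with_seed(9, {
    x <- rnorm(16000)
    bp <- band_power(matrix(x, 1), rate = 500)
    for (b in seq_len(nrow(default_bands()))) {
      bd <- default_bands()[b, ]
      v <- brickwall_var(x, bd$low, bd$high, 500)
      expect_equal(bp[[paste0("ch1_", bd$name)]], v, tolerance = 0.10)
    }
  })
})

test_that("CSP recovers the discriminative channels on the toy problem", {
  es <- toy_csp_epochs()
  m <- fit_csp(es, n_components = 2)
  w1 <- m$filters[, 1]
  expect_gt(abs(w1[1]) / abs(w1[2]), 100)   # concentrated on channel 1
  expect_equal(m$eigenvalues, c(1, 0), tolerance = 1e-4)
  expect_equal(sort(m$class_order), c("normal", "sleepy"))
})

test_that("CSP matches the brute-force generalized eigen oracle", {
  # 2-channel toy
  es2 <- toy_csp_epochs()
  fit2 <- fit_csp(es2, n_components = 2, regularization = 0)
  or2 <- csp_oracle(class_avg_cov(es2, "normal"), class_avg_cov(es2, "sleepy"))
  expect_equal(fit2$eigenvalues, or2$values[c(1, 2)], tolerance = 1e-8)
  for (j in 1:2) {
    w <- fit2$filters[, j]; v <- or2$vectors[, j]
    cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }

  # 4-channel random-covariance problem
  es4 <- withr::with_seed(13, {
    mats <- c(
      lapply(1:40, function(i) diag(c(2, 1, 0.5, 1)) %*% matrix(rnorm(4 * 300), 4)),
      lapply(1:40, function(i) diag(c(0.5, 1, 2, 1)) %*% matrix(rnorm(4 * 300), 4))
    )
    epochs_from_matrices(mats, rep(c("normal", "sleepy"), each = 40), rate = 100)
  })
  fit4 <- fit_csp(es4, n_components = 4, regularization = 0)
  or4 <- csp_oracle(class_avg_cov(es4, "normal"), class_avg_cov(es4, "sleepy"))
  expect_equal(fit4$eigenvalues, or4$values[c(1, 2, 3, 4)], tolerance = 1e-8)
  for (j in 1:4) {
    w <- fit4$filters[, j]; v <- or4$vectors[, j]
    cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
    expect_equal(cosang, 1, tolerance = 1e-6)
  }
})

test_that("CSP eigenvalues pair to one when the classes are swapped", {
  es <- toy_csp_epochs()
  m1 <- fit_csp(es, n_components = 2, regularization = 0)
  flip <- es
  flip$label <- ifelse(es$label == "sleepy", "aa_sleepy", "zz_normal")
  m2 <- fit_csp(flip, n_components = 2, regularization = 0)
  expect_equal(m1$eigenvalues + rev(m2$eigenvalues), c(1, 1), tolerance = 1e-9)
})

test_that("identical class covariances give eigenvalues of one half", {
  withr::with_seed(5, {
    mats <- lapply(1:60, function(i) matrix(rnorm(2 * 5000), 2))
    es <- epochs_from_matrices(mats, rep(c("sleepy", "normal"), 30), rate = 100)
    m <- fit_csp(es, n_components = 2)
    expect_equal(m$eigenvalues, c(0.5, 0.5), tolerance = 0.05)
  })
})

test_that("no random spatial filter beats the leading CSP filter", {
  es <- toy_csp_epochs()
  Ca <- class_avg_cov(es, "normal")
  Cb <- class_avg_cov(es, "sleepy")
  m <- fit_csp(es, n_components = 2, regularization = 0)
  ratio <- function(w) drop((t(w) %*% Ca %*% w) / (t(w) %*% (Ca + Cb) %*% w))
  best <- ratio(m$filters[, 1])
  withr::with_seed(17, {
    draws <- matrix(rnorm(2 * 1000), 2)
    rand <- apply(draws, 2, ratio)
  })
  expect_true(all(rand <= best + 1e-12))
})

test_that("CSP features separate the toy classes and have the right shape", {
  es <- toy_csp_epochs()
  m <- fit_csp(es, n_components = 2)
  fm <- apply_csp(m, es)
  expect_equal(ncol(fm) - 1L, 2L)          # label + n_components columns
  f1 <- split(fm$csp1, fm$label)
  pooled_sd <- sqrt((stats::var(f1[[1]]) + stats::var(f1[[2]])) / 2)
  expect_gt(abs(mean(f1[[1]]) - mean(f1[[2]])), 2 * pooled_sd)

  zero <- epochs_from_matrices(list(matrix(0, 2, 200)), "sleepy", rate = 100)
  expect_error(apply_csp(m, zero), "Degenerate")
  bad <- epochs_from_matrices(list(matrix(1.0 * rnorm(300), 3)), "sleepy", rate = 100)
  expect_error(apply_csp(m, bad), "channels")
})

test_that("feature concatenation stacks columns and preserves labels", {
  es <- small_sim_epochs(n_subjects = 2, duration = 6, seed = 31)
  bp <- bp_features(es)                     # 8 ch x 4 bands = 32 columns
  csp <- apply_csp(fit_csp(es, 4), es)      # 4 columns
  both <- concat_features(bp, csp)
  expect_equal(ncol(both) - 1L, 36L)
  expect_identical(both$label, bp$label)
  empty <- new_feature_matrix(matrix(numeric(0), nrow(bp), 0), bp$label)
  expect_identical(concat_features(bp, empty), bp)
  expect_error(concat_features(bp, csp[1:3, ]), "identical")
})
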