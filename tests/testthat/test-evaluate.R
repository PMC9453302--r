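test_that("holdout split is stratified, disjoint and reproducible", {
  es <- toy_band_epochs(n_per_class = 500, nch = 1, n = 50)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.2, seed = 5))
  expect_equal(nrow(sp$heldout), 200L)
  expect_equal(as.vector(table(sp$heldout$label)), c(100L, 100L))
  expect_length(intersect(sp$train$epoch_id, sp$heldout$epoch_id), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$heldout), 1000L)

  sp2 <- holdout_split(es, split_spec("holdout", test_fraction = 0.2, seed = 5))
  expect_identical(sort(sp$heldout$epoch_id), sort(sp2$heldout$epoch_id))

  expect_error(split_spec("holdout", test_fraction = 0), "between")
  expect_error(split_spec("holdout", test_fraction = 1), "between")
})

test_that("subject-grouped holdout keeps subjects on one side", {
  es <- toy_band_epochs(n_per_class = 40, nch = 1, n = 50)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.25,
                                     seed = 2, group_by_subject = TRUE))
  expect_length(intersect(unique(sp$train$subject_id),
                          unique(sp$heldout$subject_id)), 0L)
})

test_that("k-fold partitions are balanced, disjoint and exhaustive", {
  es <- toy_band_epochs(n_per_class = 50, nch = 1, n = 50)  # n = 100
  folds <- kfold_split(es, split_spec("kfold", k = 10, seed = 1))
  expect_length(folds, 10L)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes == 10L))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_len(100L))
  for (f in folds) expect_length(intersect(f$train, f$test), 0L)

  # class proportions per fold within one epoch of global proportions
  for (f in folds) {
    tab <- table(es$label[f$test])
    expect_lte(abs(tab[["sleepy"]] - tab[["normal"]]), 1L)
  }
})

test_that("uneven and degenerate fold counts follow the balanced rule", {
  es95 <- toy_band_epochs(n_per_class = 50, nch = 1, n = 50)
  es95 <- new_epoch_set(es95[1:95, ], 500, attr(es95, "window"))
  sizes <- sort(vapply(kfold_split(es95, split_spec("kfold", k = 10, seed = 3)),
                       function(f) length(f$test), integer(1)))
  expect_identical(sizes, rep(c(9L, 10L), each = 5L))

  es10 <- new_epoch_set(es95[1:10, ], 500, attr(es95, "window"))
  loo <- kfold_split(es10, split_spec("kfold", k = 10, seed = 1))
  expect_true(all(vapply(loo, function(f) length(f$test), integer(1)) == 1L))
  expect_error(kfold_split(es10, split_spec("kfold", k = 11)), "exceed")
})

test_that("confusion metrics reproduce hand-computed values", {
  # truth and scores engineered to give tp=9, fp=1, fn=1, tn=9
  y <- rep(c("sleepy", "normal"), each = 10)
  s <- c(rep(0.9, 9), 0.1, rep(0.1, 9), 0.9)
  r <- compute_metrics(y, s)
  expect_identical(r$confusion[c("tp", "fp", "fn", "tn")],
                   list(tp = 9L, fp = 1L, fn = 1L, tn = 9L))
  expect_equal(r$accuracy, 0.9)
  m <- r$metrics[r$metrics$class == "sleepy", ]
  expect_equal(m$precision, 0.9)
  expect_equal(m$f1, 0.9)

  perfect <- compute_metrics(y, ifelse(y == "sleepy", 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$metrics$precision, c(1, 1))
  expect_equal(perfect$metrics$f1, c(1, 1))
  expect_equal(perfect$auc, 1)
})

test_that("degenerate all-negative predictions flag undefined precision", {
  y <- c("sleepy", "normal", "normal")
  r <- compute_metrics(y, c(0.1, 0.2, 0.3))
  pos_row <- r$metrics[r$metrics$class == "sleepy", ]
  expect_true(pos_row$precision_undefined)
  expect_equal(pos_row$precision, 0)
  expect_equal(r$accuracy, 2 / 3)
  expect_error(compute_metrics(character(0), numeric(0)), "Empty")
})

test_that("F1 is the harmonic mean and accuracy survives relabeling", {
  withr::with_seed(11, {
    for (i in 1:20) {
      y <- sample(c("sleepy", "normal"), 40, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- runif(40)
      r <- compute_metrics(y, s)
      m <- r$metrics
      for (j in 1:2) {
        pr <- m$precision[j]; rc <- m$recall[j]
        f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
        expect_equal(m$f1[j], f1)
      }
      # swapping the positive class leaves accuracy invariant
      r2 <- compute_metrics(y, 1 - s, positive = "normal")
      expect_equal(r2$accuracy, mean((1 - s >= 0.5) == (y == "normal")))
    }
  })
})

test_that("ROC endpoints, symmetry and null behaviour are correct", {
  y <- rep(c("sleepy", "normal"), each = 20)
  s_perf <- ifelse(y == "sleepy", 0.8, 0.2)
  rc <- roc_curve(y, s_perf)
  expect_equal(attr(rc, "auc"), 1)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))

  withr::with_seed(23, {
    yy <- rep(c("sleepy", "normal"), each = 500)
    ss <- runif(1000)
    auc_null <- attr(roc_curve(yy, ss), "auc")
    expect_equal(auc_null, 0.5, tolerance = 0.1)
    # score reversal maps AUC to its complement
    auc_rev <- attr(roc_curve(yy, 1 - ss), "auc")
    expect_equal(auc_rev, 1 - auc_null, tolerance = 1e-9)
  })
  expect_error(roc_curve(rep("sleepy", 5), runif(5)), "both classes")
})

test_that("trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    y <- rep(c("sleepy", "normal"), each = 100)
    s <- ifelse(y == "sleepy", rnorm(100, 0.6, 0.2), rnorm(100, 0.4, 0.2))
    ours <- attr(roc_curve(y, s), "auc")
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("normal", "sleepy"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-9)
  })
})

test_that("run_cv returns one fitted model per fold and honest summaries", {
  es <- toy_band_epochs(n_per_class = 100, nch = 2, n = 200)
  cv <- run_cv(es, split_spec("kfold", k = 10, seed = 7),
               classical_model("lda", "bp"))
  expect_length(cv$fitted_models, 10L)
  expect_length(cv$fold_reports, 10L)
  accs <- vapply(cv$fold_reports, `[[`, numeric(1), "accuracy")
  expect_equal(cv$mean_accuracy, mean(accs))
  expect_equal(cv$sd_accuracy, sd(accs))
  expect_gt(cv$mean_accuracy, 0.9)   # separable toy problem
})

test_that("a constant-score dummy model sits at chance on balanced data", {
  es <- toy_band_epochs(n_per_class = 100, nch = 1, n = 50)
  cv <- run_cv(es, split_spec("kfold", k = 5, seed = 9), dummy_model(0.4))
  # scores below threshold everywhere -> predicts the negative class always
  expect_equal(cv$mean_accuracy, 0.5, tolerance = 0.01)
})

test_that("augmentation in CV touches training folds only (no leakage)", {
  es <- toy_band_epochs(n_per_class = 30, nch = 1, n = 250)
  seen <- new.env()
  spy <- structure(list(
    fit = function(tr) {
      seen$trains <- c(seen$trains %||% list(), list(tr))
      classical_model("lda", "bp")$fit(tr)
    },
    score = classical_model("lda", "bp")$score,
    label = "spy"), class = "model_builder")
  cv <- run_cv(es, split_spec("kfold", k = 5, seed = 3), spy,
               augment_spec = augment_spec(copies_per_epoch = 2, seed = 4))
  folds <- cv$fold_indices
  for (f in seq_along(folds)) {
    tr <- seen$trains[[f]]
    test_ids <- es$epoch_id[folds[[f]]$test]
    expect_equal(nrow(tr), 3L * length(folds[[f]]$train))
    # no augmented training epoch derives from a test epoch
    expect_length(intersect(tr$source_id, test_ids), 0L)
  }
  expect_error(run_cv(augment_epochset(es, augment_spec(copies_per_epoch = 1)),
                      split_spec("kfold", k = 5), dummy_model()),
               "original")
})

test_that("baseline suite recovers separable features and fails shuffled ones", {
  withr::with_seed(41, {
    n <- 200
    labels <- rep(c("sleepy", "normal"), each = n / 2)
    sep <- new_feature_matrix(
      cbind(f1 = ifelse(labels == "sleepy", 1, -1) + rnorm(n, 0, 0.1),
            f2 = rnorm(n)), labels)
    shuf <- new_feature_matrix(matrix(rnorm(n * 2), n,
                                      dimnames = list(NULL, c("f1", "f2"))),
                               labels)
    tab <- run_baseline_suite(list(BP = sep, CSP = sep, `BP+CSP` = sep),
                              split_spec("holdout", seed = 1))
    expect_identical(tab$feature_set, c("BP", "CSP", "BP+CSP"))
    expect_identical(names(tab), c("feature_set", "Tree", "LDA", "SVM", "KNN"))
    expect_true(all(as.matrix(tab[, -1]) >= 0.95))

    null_tab <- run_baseline_suite(list(BP = shuf),
                                   split_spec("kfold", k = 5, seed = 2))
    expect_true(all(abs(as.matrix(null_tab[, -1]) - 0.5) <= 0.12))
  })
})

test_that("mismatched feature sets are rejected by the baseline suite", {
  labels <- rep(c("sleepy", "normal"), 10)
  a <- new_feature_matrix(matrix(rnorm(40), 20,
                                 dimnames = list(NULL, c("x", "y"))), labels)
  b <- new_feature_matrix(matrix(rnorm(38), 19,
                                 dimnames = list(NULL, c("x", "y"))),
                          labels[1:19])
  expect_error(run_baseline_suite(list(A = a, B = b)), "identical")
})
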