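#' Data-splitting specification
#'
#' Configures either a stratified 80/20-style holdout or shuffled k-fold
#' cross-validation with k = 10 by default.
#'
#' @param kind `"holdout"` or `"kfold"`.
#' @param test_fraction Held-out fraction for holdout splits, in `(0, 1)`.
#' @param k Number of folds for k-fold splits (>= 2).
#' @param shuffle Shuffle before partitioning.
#' @param seed Integer seed controlling the shuffle.
#' @param group_by_subject Keep every subject entirely on one side of a
#'   holdout split (honest subject-level generalization). Off by default.
#' @return A `split_spec` object.
#' @export
split_spec <- function(kind = c("holdout", "kfold"), test_fraction = 0.2,
                       k = 10, shuffle = TRUE, seed = 1L,
                       group_by_subject = FALSE) {
  kind <- match.arg(kind)
  if (kind == "holdout") {
    assert_scalar_number(test_fraction, "test_fraction")
    if (test_fraction <= 0 || test_fraction >= 1) {
      abort_bad_arg("`test_fraction` must be strictly between 0 and 1.")
    }
  } else {
    k <- assert_count(k, "k", min = 2L)
  }
  structure(list(kind = kind, test_fraction = test_fraction,
                 k = as.integer(k), shuffle = isTRUE(shuffle),
                 seed = as.integer(seed),
                 group_by_subject = isTRUE(group_by_subject)),
            class = "split_spec")
}

#' Stratified holdout split
#'
#' Holds out `test_fraction` of the epochs, stratified by class so both
#' categories contribute the same fraction (within one epoch per class).
#' With `group_by_subject = TRUE`, whole subjects are assigned to the
#' held-out side until the fraction is reached, so no subject spans both
#' sides (stratification is then approximate).
#'
#' @param es An `epoch_set`.
#' @param spec A [split_spec()] with `kind = "holdout"`.
#' @return List with elements `train` and `heldout` (both `epoch_set`s).
#' @export
holdout_split <- function(es, spec = split_spec("holdout")) {
  stopifnot(inherits(es, "epoch_set"), inherits(spec, "split_spec"))
  if (spec$kind != "holdout") abort_bad_arg("`spec` must have kind 'holdout'.")
  n <- nrow(es)
  test_idx <- withr::with_seed(spec$seed, {
    if (spec$group_by_subject) {
      subj <- unique(es$subject_id)
      subj <- if (spec$shuffle) sample(subj) else subj
      target <- spec$test_fraction * n
      take <- character(0); got <- 0
      for (s in subj) {
        if (got >= target) break
        take <- c(take, s)
        got <- got + sum(es$subject_id == s)
      }
      which(es$subject_id %in% take)
    } else {
      unlist(lapply(split(seq_len(n), es$label), function(idx) {
        m <- round(length(idx) * spec$test_fraction)
        if (spec$shuffle) idx <- sample(idx)
        idx[seq_len(m)]
      }), use.names = FALSE)
    }
  })
  if (length(test_idx) == 0L || length(test_idx) == n) {
    abort_bad_arg("`test_fraction` leaves an empty train or heldout side.")
  }
  list(
    train = restore_epoch_set(es[-test_idx, , drop = FALSE], es),
    heldout = restore_epoch_set(es[test_idx, , drop = FALSE], es)
  )
}

#' Shuffled, stratified k-fold partitions
#'
#' Deals the (shuffled) epochs of each class round-robin into `k` folds,
#' so test folds are pairwise disjoint, their union is the full index set,
#' fold sizes differ by at most one, and class proportions per fold stay
#' within one epoch of the global proportions.
#'
#' @param es An `epoch_set` (or anything with `nrow`); only labels are
#'   consulted.
#' @param spec A [split_spec()] with `kind = "kfold"` and `k <= n`.
#' @return List of `k` elements, each `list(train, test)` of integer row
#'   indices.
#' @export
kfold_split <- function(es, spec = split_spec("kfold")) {
  stopifnot(inherits(spec, "split_spec"))
  if (spec$kind != "kfold") abort_bad_arg("`spec` must have kind 'kfold'.")
  n <- nrow(es)
  if (spec$k > n) abort_bad_arg("`k` cannot exceed the number of epochs.")
  labels <- if ("label" %in% names(es)) es$label else rep("all", n)
  folds <- withr::with_seed(spec$seed, {
    fold_of <- integer(n)
    pos <- 0L
    for (lbl in unique(labels)) {
      idx <- which(labels == lbl)
      if (spec$shuffle) idx <- sample(idx)
      fold_of[idx] <- ((pos + seq_along(idx) - 1L) %% spec$k) + 1L
      pos <- pos + length(idx)
    }
    fold_of
  })
  lapply(seq_len(spec$k), function(f) {
    list(train = which(folds != f), test = which(folds == f))
  })
}

#' Confusion-matrix metrics, ROC and AUC for scored predictions
#'
#' Thresholds the scores at `positive_threshold`, forms the confusion
#' matrix for the positive class and reports accuracy
#' `(tp + tn) / n`, precision `tp / (tp + fp)`, recall `tp / (tp + fn)`
#' and the F1 harmonic mean - each also computed with the positive class
#' swapped, giving Table-style per-class rows. An undefined precision
#' (no positive predictions) is reported as 0 and flagged. The full ROC
#' curve and trapezoid AUC are attached when both classes are present.
#'
#' @param y_true True labels (two classes).
#' @param y_score Score in `[0, 1]`: the probability of the positive
#'   class.
#' @param positive_threshold Classification threshold on the score.
#' @param positive Which label is the positive class; defaults to
#'   `"sleepy"` when present, otherwise the first label alphabetically.
#' @return An `eval_report`: accuracy, per-class metric tibble, confusion
#'   counts, ROC tibble, AUC, threshold and n.
#' @export
compute_metrics <- function(y_true, y_score, positive_threshold = 0.5,
                            positive = NULL) {
  y_true <- as.character(y_true)
  if (length(y_true) == 0L) abort_bad_arg("Empty input.")
  if (length(y_true) != length(y_score)) {
    abort_bad_arg("`y_true` and `y_score` must have equal length.")
  }
  classes <- sort(unique(y_true))
  positive <- positive %||% if ("sleepy" %in% classes) "sleepy" else classes[1]
  negative <- setdiff(classes, positive)
  negative <- if (length(negative) == 0) paste0("not_", positive) else negative[1]

  one_class <- function(pos, truth_pos, pred_pos) {
    tp <- sum(pred_pos & truth_pos)
    fp <- sum(pred_pos & !truth_pos)
    fn <- sum(!pred_pos & truth_pos)
    tn <- sum(!pred_pos & !truth_pos)
    undef <- (tp + fp) == 0L
    precision <- if (undef) 0 else tp / (tp + fp)
    recall <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = pos, precision = precision, recall = recall,
                   f1 = f1, support = sum(truth_pos),
                   precision_undefined = undef)
  }
  truth_pos <- y_true == positive
  pred_pos <- y_score >= positive_threshold
  metrics <- dplyr::bind_rows(
    one_class(positive, truth_pos, pred_pos),
    one_class(negative, !truth_pos, !pred_pos)
  )
  confusion <- list(tp = sum(pred_pos & truth_pos),
                    fp = sum(pred_pos & !truth_pos),
                    fn = sum(!pred_pos & truth_pos),
                    tn = sum(!pred_pos & !truth_pos),
                    positive = positive)
  roc <- NULL; auc <- NA_real_
  if (length(unique(y_true)) == 2L) {
    roc <- roc_curve(y_true, y_score, positive = positive)
    auc <- attr(roc, "auc")
  }
  structure(
    list(accuracy = mean(pred_pos == truth_pos),
         metrics = metrics, confusion = confusion, roc = roc, auc = auc,
         positive_threshold = positive_threshold, n = length(y_true)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.3f, AUC %s (positive: %s, threshold %.2f)\n",
              x$n, x$accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$confusion$positive, x$positive_threshold))
  print(x$metrics)
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Sweeps the decision threshold over the unique scores and returns
#' (false positive rate, true positive rate, threshold) triples from
#' (0, 0) to (1, 1), plus the trapezoid-rule AUC as an attribute.
#'
#' @inheritParams compute_metrics
#' @return A `roc_curve` tibble with attribute `auc`.
#' @export
roc_curve <- function(y_true, y_score, positive = NULL) {
  y_true <- as.character(y_true)
  classes <- sort(unique(y_true))
  if (length(classes) != 2L) {
    abort_bad_arg("ROC needs both classes present in `y_true`.")
  }
  positive <- positive %||% if ("sleepy" %in% classes) "sleepy" else classes[1]
  truth <- y_true == positive
  ths <- c(Inf, sort(unique(y_score), decreasing = TRUE))
  P <- sum(truth); N <- sum(!truth)
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- y_score >= ths[i]
    tpr[i] <- sum(pred & truth) / P
    fpr[i] <- sum(pred & !truth) / N
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble::tibble(threshold = ths, fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  class(out) <- c("roc_curve", class(out))
  out
}

#' Model builders for the evaluation harness
#'
#' A model builder couples a fitting routine with a scoring routine so the
#' cross-validation harness can treat classical pipelines and the
#' convolutional network uniformly. `classical_model()` extracts band
#' power and/or CSP features (fitting the CSP filters on the training fold
#' only) and trains one of the four baseline classifiers;
#' `cnn_model()` carves an internal validation subset out of each
#' training fold for early stopping and trains the compact network;
#' `dummy_model()` predicts a constant score (chance-level control).
#'
#' @param classifier One of `"svm"` (RBF kernel), `"lda"`, `"knn"`
#'   (k = 5), `"tree"`.
#' @param features `"bp"`, `"csp"` or `"bp+csp"`.
#' @param bands Band table for band-power features.
#' @param n_csp CSP component count.
#' @param knn_k Neighbour count for `"knn"`.
#' @return A `model_builder` with elements `fit(es)` and
#'   `score(fit, es)`; the score is the probability of the positive
#'   class (`"sleepy"` when present).
#' @export
classical_model <- function(classifier = c("svm", "lda", "knn", "tree"),
                            features = c("bp+csp", "bp", "csp"),
                            bands = default_bands(), n_csp = 4, knn_k = 5) {
  classifier <- match.arg(classifier)
  features <- match.arg(features)
  extract <- function(es, csp) {
    fm <- NULL
    if (features %in% c("bp", "bp+csp")) fm <- bp_features(es, bands = bands)
    if (features %in% c("csp", "bp+csp")) {
      cf <- apply_csp(csp, es)
      fm <- if (is.null(fm)) cf else concat_features(fm, cf)
    }
    fm
  }
  fit <- function(es) {
    csp <- if (features %in% c("csp", "bp+csp")) fit_csp(es, n_components = n_csp)
           else NULL
    fm <- extract(es, csp)
    cls <- fit_classifier(fm, classifier, knn_k = knn_k)
    list(csp = csp, cls = cls, classifier = classifier)
  }
  score <- function(fitted, es) {
    fm <- extract(es, fitted$csp)
    score_classifier(fitted$cls, fm)
  }
  structure(list(fit = fit, score = score,
                 label = paste(classifier, features)),
            class = "model_builder")
}

#' @rdname classical_model
#' @param config A `network_config`; default [build_compact_net()] sized
#'   to the data at fit time.
#' @param val_fraction Fraction of each training fold held out internally
#'   for early stopping.
#' @export
cnn_model <- function(config = NULL, val_fraction = 0.1) {
  fit <- function(es) {
    cfg <- config %||% build_compact_net(dim(es$signal[[1]]))
    sp <- holdout_split(es, split_spec("holdout",
                                       test_fraction = val_fraction,
                                       seed = cfg$seed))
    train_network(cfg, sp$train, sp$heldout)
  }
  score <- function(fitted, es) {
    pr <- predict(fitted, es, type = "prob")
    pos <- if ("sleepy" %in% names(pr)) "sleepy" else names(pr)[1]
    pr[[pos]]
  }
  structure(list(fit = fit, score = score, label = "compact CNN"),
            class = "model_builder")
}

#' @rdname classical_model
#' @param constant Constant score returned for every epoch.
#' @export
dummy_model <- function(constant = 0.5) {
  structure(list(fit = function(es) constant,
                 score = function(fitted, es) rep(fitted, nrow(es)),
                 label = "dummy"),
            class = "model_builder")
}

# classical classifier fit/score on a feature_matrix ------------------------

fit_classifier <- function(fm, classifier, knn_k = 5) {
  df <- as.data.frame(fm)
  df$label <- factor(df$label)
  pos <- if ("sleepy" %in% levels(df$label)) "sleepy" else levels(df$label)[1]
  obj <- switch(classifier,
    tree = rpart::rpart(label ~ ., data = df, method = "class"),
    lda  = MASS::lda(label ~ ., data = df),
    svm  = e1071::svm(label ~ ., data = df, kernel = "radial",
                      probability = TRUE),
    knn  = list(train = feature_values(fm), cl = df$label, k = knn_k)
  )
  list(kind = classifier, obj = obj, positive = pos)
}

score_classifier <- function(cls, fm) {
  newx <- as.data.frame(fm)
  switch(cls$kind,
    tree = stats::predict(cls$obj, newx, type = "prob")[, cls$positive],
    lda  = stats::predict(cls$obj, newx)$posterior[, cls$positive],
    svm  = {
      pr <- stats::predict(cls$obj, newx, probability = TRUE)
      attr(pr, "probabilities")[, cls$positive]
    },
    knn  = {
      pred <- class::knn(cls$obj$train, feature_values(fm), cls$obj$cl,
                         k = cls$obj$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == cls$positive, p, 1 - p)
    }
  )
}

#' k-fold cross-validation of a model builder
#'
#' Trains one model per fold on that fold's training side and scores the
#' left-out fold. Augmentation, when requested, is applied after
#' splitting and only to the training side, so no augmented copy of a
#' test epoch can leak into training. Fold metrics come from
#' [compute_metrics()]; the summary reports their mean and standard
#' deviation.
#'
#' @param es An `epoch_set` of original (non-augmented) epochs.
#' @param spec A [split_spec()] with `kind = "kfold"`.
#' @param model_builder A builder from [classical_model()], [cnn_model()]
#'   or [dummy_model()].
#' @param augment_spec Optional [augment_spec()] applied to each training
#'   fold.
#' @param positive_threshold Threshold passed to [compute_metrics()].
#' @param verbose Print per-fold accuracy.
#' @return A `cv_result`: `fold_reports` (list of `eval_report`s),
#'   `mean_accuracy`, `sd_accuracy`, `fitted_models`, `fold_indices` and
#'   the spec.
#' @export
run_cv <- function(es, spec = split_spec("kfold"), model_builder,
                   augment_spec = NULL, positive_threshold = 0.5,
                   verbose = FALSE) {
  stopifnot(inherits(es, "epoch_set"), inherits(model_builder, "model_builder"))
  if (any(es$augmented)) {
    abort_bad_arg("`es` must contain original epochs only; augmentation happens per fold.")
  }
  folds <- kfold_split(es, spec)
  reports <- vector("list", length(folds))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- restore_epoch_set(es[folds[[f]]$train, , drop = FALSE], es)
    te <- restore_epoch_set(es[folds[[f]]$test, , drop = FALSE], es)
    if (length(unique(tr$label)) < 2L) {
      abort_bad_arg(sprintf("Fold %d has a single-class training side.", f))
    }
    if (!is.null(augment_spec)) tr <- augment_epochset(tr, augment_spec)
    fitted <- model_builder$fit(tr)
    scores <- model_builder$score(fitted, te)
    reports[[f]] <- compute_metrics(te$label, scores,
                                    positive_threshold = positive_threshold)
    models[[f]] <- fitted
    if (verbose) {
      message(sprintf("fold %2d: accuracy %.3f", f, reports[[f]]$accuracy))
    }
  }
  accs <- vapply(reports, `[[`, numeric(1), "accuracy")
  structure(
    list(fold_reports = reports, mean_accuracy = mean(accs),
         sd_accuracy = stats::sd(accs), fitted_models = models,
         fold_indices = folds, spec = spec, model = model_builder$label),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d folds, accuracy %.3f +/- %.3f\n",
              x$model, length(x$fold_reports), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Classical baseline accuracy table
#'
#' Evaluates the decision tree, LDA, RBF-kernel SVM and k-NN classifiers
#' on each provided feature set under identical splits, yielding the
#' feature-set x classifier accuracy table of the classical baseline
#' comparison (rows BP, CSP, BP+CSP when all three sets are given).
#'
#' @param features_by_set Named list of `feature_matrix` objects covering
#'   identical epochs in identical order (e.g. `list(BP = ..., CSP = ...,
#'   "BP+CSP" = ...)`).
#' @param spec A [split_spec()]; a holdout spec evaluates one split, a
#'   kfold spec reports the mean CV accuracy.
#' @param classifiers Classifier subset to run.
#' @param knn_k Neighbour count for k-NN.
#' @return Tibble with one row per feature set and one accuracy column
#'   per classifier (`Tree`, `LDA`, `SVM`, `KNN`).
#' @export
run_baseline_suite <- function(features_by_set,
                               spec = split_spec("holdout"),
                               classifiers = c("tree", "lda", "svm", "knn"),
                               knn_k = 5) {
  stopifnot(is.list(features_by_set), length(features_by_set) > 0)
  labs <- lapply(features_by_set, function(fm) fm$label)
  if (length(unique(vapply(labs, length, integer(1)))) != 1L ||
      !all(vapply(labs, identical, logical(1), labs[[1]]))) {
    abort_bad_arg("All feature sets must cover identical epochs in the same order.")
  }
  n <- length(labs[[1]])
  splits <- if (spec$kind == "holdout") {
    idx <- withr::with_seed(spec$seed, {
      unlist(lapply(split(seq_len(n), labs[[1]]), function(i) {
        m <- round(length(i) * spec$test_fraction)
        if (spec$shuffle) i <- sample(i)
        i[seq_len(m)]
      }), use.names = FALSE)
    })
    list(list(train = setdiff(seq_len(n), idx), test = idx))
  } else {
    kfold_split(features_by_set[[1]], spec)
  }
  col_name <- c(tree = "Tree", lda = "LDA", svm = "SVM", knn = "KNN")
  out <- tibble::tibble(feature_set = names(features_by_set))
  for (cl in classifiers) {
    accs <- vapply(features_by_set, function(fm) {
      fold_accs <- vapply(splits, function(sp) {
        tr <- fm[sp$train, , drop = FALSE]
        te <- fm[sp$test, , drop = FALSE]
        fitted <- fit_classifier(tr, cl, knn_k = knn_k)
        sc <- score_classifier(fitted, te)
        mean((sc >= 0.5) == (te$label == fitted$positive))
      }, numeric(1))
      mean(fold_accs)
    }, numeric(1))
    out[[col_name[[cl]]]] <- accs
  }
  out
}
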