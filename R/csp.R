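#' Feature matrices
#'
#' A `feature_matrix` is a tibble with one row per epoch: a `label` column
#' followed by numeric feature columns. Constructed by [bp_features()],
#' [apply_csp()] or [concat_features()].
#'
#' @param values Numeric matrix, epochs x features, with column names.
#' @param labels Class label per epoch.
#' @return A `feature_matrix` tibble.
#' @export
new_feature_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) abort_bad_arg("Features must be finite.")
  if (nrow(values) != length(labels)) {
    abort_bad_arg("Row count of `values` must equal the number of labels.")
  }
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(label = as.character(labels)), out)
  class(out) <- c("feature_matrix", class(out))
  out
}

feature_values <- function(fm) {
  as.matrix(fm[, setdiff(names(fm), "label"), drop = FALSE])
}

#' Fit common spatial patterns (CSP)
#'
#' Two-class CSP: finds spatial filters `w` maximizing the variance ratio
#' between classes by solving the generalized eigenproblem
#' `C_A w = lambda (C_A + C_B) w` on the class-average covariances. Each
#' epoch's covariance is trace-normalized before averaging so that epochs
#' contribute equally regardless of amplitude, and the composite covariance
#' is ridge-shrunk by `regularization` toward a scaled identity to keep the
#' problem well posed. Eigenvalues lie in `[0, 1]`: a value near 1 marks a
#' direction where class A dominates, near 0 where class B does. The
#' returned filters are the `n_components/2` most class-A and
#' `n_components/2` most class-B discriminative directions.
#'
#' @param es An `epoch_set` containing exactly two classes.
#' @param n_components Even number of spatial filters to keep (at most the
#'   channel count).
#' @param regularization Shrinkage weight in `[0, 1)`.
#' @return A `csp_model`: list with `filters` (channels x components),
#'   `eigenvalues` (descending), `n_components` and `class_order`.
#' @export
fit_csp <- function(es, n_components = 4, regularization = 1e-6) {
  stopifnot(inherits(es, "epoch_set"))
  n_components <- assert_count(n_components, "n_components")
  if (n_components %% 2L != 0L) abort_bad_arg("`n_components` must be even.")
  if (regularization < 0 || regularization >= 1) {
    abort_bad_arg("`regularization` must be in [0, 1).")
  }
  classes <- sort(unique(es$label))
  if (length(classes) != 2L) {
    abort_bad_arg("CSP needs exactly two classes present in the epoch_set.")
  }
  p <- nrow(es$signal[[1]])
  if (n_components > p) abort_bad_arg("`n_components` exceeds the channel count.")

  class_cov <- function(lbl) {
    idx <- which(es$label == lbl)
    acc <- matrix(0, p, p)
    for (i in idx) {
      x <- es$signal[[i]]
      x <- x - rowMeans(x)
      cc <- tcrossprod(x)
      tr <- sum(diag(cc))
      if (tr > 0) acc <- acc + cc / tr
    }
    acc / length(idx)
  }
  Ca <- class_cov(classes[1])
  Cb <- class_cov(classes[2])
  Cc <- Ca + Cb
  if (regularization > 0) {
    Cc <- (1 - regularization) * Cc +
      regularization * (sum(diag(Cc)) / p) * diag(p)
  }
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= .Machine$double.eps * max(ec$values)) {
    abort_bad_arg("Composite covariance is singular; increase `regularization`.")
  }
  # whiten, then diagonalize class A in the whitened space
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S <- P %*% Ca %*% t(P)
  es2 <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- t(P) %*% es2$vectors              # generalized eigenvectors, descending
  lam <- pmin(pmax(es2$values, 0), 1)
  half <- n_components %/% 2L
  pick <- c(seq_len(half), p - half + seq_len(half))
  structure(
    list(filters = W[, pick, drop = FALSE],
         eigenvalues = lam[pick],
         n_components = as.integer(n_components),
         class_order = classes),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d components (%s vs %s)\n  eigenvalues: %s\n",
              x$n_components, x$class_order[1], x$class_order[2],
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Extract CSP features from epochs
#'
#' Projects each epoch through the fitted spatial filters and returns the
#' log of each component's variance, normalized by the total variance
#' across components - the standard CSP feature.
#'
#' @param model A fitted [fit_csp()] model.
#' @param es An `epoch_set` with the channel count the model was fit on.
#' @param prefix Feature column prefix.
#' @return A `feature_matrix` with `n_components` columns.
#' @export
apply_csp <- function(model, es, prefix = "csp") {
  stopifnot(inherits(model, "csp_model"), inherits(es, "epoch_set"))
  p <- nrow(es$signal[[1]])
  if (p != nrow(model$filters)) {
    abort_bad_arg(sprintf("Epochs have %d channels but the CSP model expects %d.",
                          p, nrow(model$filters)))
  }
  W <- model$filters
  vals <- t(vapply(es$signal, function(x) {
    z <- crossprod(W, x - rowMeans(x))   # components x samples
    v <- rowSums(z^2) / (ncol(z) - 1L)
    tot <- sum(v)
    if (tot <= 0) abort_bad_arg("Degenerate epoch: zero variance after spatial filtering.")
    base::log(v / tot)
  }, numeric(ncol(W))))
  colnames(vals) <- paste0(prefix, seq_len(ncol(W)))
  new_feature_matrix(vals, es$label)
}

#' Concatenate feature matrices column-wise
#'
#' Joins two feature matrices computed over the same epochs in the same
#' order (e.g. band power + CSP). Labels must agree row by row.
#'
#' @param a,b `feature_matrix` objects.
#' @return The combined `feature_matrix`.
#' @export
concat_features <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (nrow(a) != nrow(b) || !all(a$label == b$label)) {
    abort_bad_arg("Feature matrices must cover identical epochs in the same order.")
  }
  vb <- feature_values(b)
  if (ncol(vb) == 0) return(a)
  va <- feature_values(a)
  if (ncol(va) == 0) return(b)
  new_feature_matrix(cbind(va, vb), a$label)
}
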