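#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted CSP model
#'
#' @param x A `csp_model`.
#' @param ... Unused.
#' @return Tibble with one row per spatial filter: `component`,
#'   `eigenvalue` (variance fraction of the first class) and the filter
#'   weights as `w_<channel>` columns.
#' @method tidy csp_model
#' @export
tidy.csp_model <- function(x, ...) {
  W <- t(x$filters)
  colnames(W) <- paste0("w_", rownames(x$filters) %||%
                          paste0("ch", seq_len(nrow(x$filters))))
  dplyr::bind_cols(
    tibble::tibble(component = seq_len(x$n_components),
                   eigenvalue = x$eigenvalues),
    tibble::as_tibble(as.data.frame(W))
  )
}

#' @rdname tidy.csp_model
#' @method glance csp_model
#' @export
glance.csp_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 class_a = x$class_order[1], class_b = x$class_order[2],
                 max_eigenvalue = max(x$eigenvalues),
                 min_eigenvalue = min(x$eigenvalues))
}

#' Tidy a trained network's training log
#'
#' @param x A `trained_network`.
#' @param ... Unused.
#' @return The training log as a tibble (one row per validation
#'   evaluation).
#' @method tidy trained_network
#' @export
tidy.trained_network <- function(x, ...) tibble::as_tibble(x$log)

#' @rdname tidy.trained_network
#' @method glance trained_network
#' @export
glance.trained_network <- function(x, ...) {
  i <- which.min(x$log$validation_loss)
  tibble::tibble(
    epochs_trained = nrow(x$log),
    best_epoch = x$best_epoch,
    best_validation_loss = x$log$validation_loss[i],
    best_validation_accuracy = x$log$validation_accuracy[i] / 100,
    base_learning_rate = x$config$base_learning_rate,
    n_parameters = sum(vapply(x$weights, function(p) {
      if (is.null(p)) 0L else length(p$W) + length(p$b)
    }, integer(1)))
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-class metric tibble (precision, recall, F1, support).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc, n = x$n,
                 positive = x$confusion$positive,
                 threshold = x$positive_threshold,
                 tp = x$confusion$tp, fp = x$confusion$fp,
                 fn = x$confusion$fn, tn = x$confusion$tn)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `accuracy`, `auc`, `n`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$fold_reports),
    accuracy = vapply(x$fold_reports, `[[`, numeric(1), "accuracy"),
    auc = vapply(x$fold_reports, `[[`, numeric(1), "auc"),
    n = vapply(x$fold_reports, `[[`, numeric(1), "n")
  )
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(model = x$model, k = length(x$fold_reports),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}
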