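#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_curve
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) {
    abort_bad_arg("This eval_report has no ROC curve (single-class truth).")
  }
  autoplot(object$roc) +
    ggplot2::labs(subtitle = sprintf("accuracy %.3f at threshold %.2f",
                                     object$accuracy,
                                     object$positive_threshold))
}

#' Plot a training log
#'
#' Validation accuracy and loss against training epoch, the usual
#' convergence picture (loss falling, accuracy rising).
#'
#' @param object A `training_log` (e.g. `fit$log` or `tidy(fit)`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot training_log
#' @export
autoplot.training_log <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = df$epoch, value = df$validation_accuracy / 100,
                   metric = "validation accuracy"),
    tibble::tibble(epoch = df$epoch, value = df$validation_loss,
                   metric = "validation loss")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Welch power spectral density
#'
#' @param object A [welch_psd()] tibble.
#' @param ... Unused.
#' @return A ggplot of density against frequency per channel.
#' @method autoplot welch_psd
#' @export
autoplot.welch_psd <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frequency, y = .data$density,
                               colour = .data$channel)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(paste(mu, V^2, "/Hz")),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
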