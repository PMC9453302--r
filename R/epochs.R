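#' Epoch sets: labeled fixed-length EEG windows
#'
#' An `epoch_set` is a tibble with one row per epoch and the columns
#' `epoch_id` (unique integer), `source_id` (the originating epoch for
#' augmented copies; equals `epoch_id` for originals), `subject_id`,
#' `session_id`, `label`, `start_offset` (seconds into the recording),
#' `augmented` (logical) and `signal` (list-column of channels x samples
#' matrices). The sampling rate and window length travel as attributes.
#'
#' @param df Data frame with the columns above (missing bookkeeping
#'   columns are filled in).
#' @param sampling_rate Sampling rate in Hz.
#' @param window Window length in seconds.
#' @return An `epoch_set` tibble.
#' @export
new_epoch_set <- function(df, sampling_rate, window) {
  df <- tibble::as_tibble(df)
  if (!"signal" %in% names(df)) abort_bad_arg("`df` needs a `signal` list-column.")
  n <- nrow(df)
  if (!"epoch_id" %in% names(df)) df$epoch_id <- seq_len(n)
  if (!"source_id" %in% names(df)) df$source_id <- df$epoch_id
  if (!"augmented" %in% names(df)) df$augmented <- FALSE
  if (!"start_offset" %in% names(df)) df$start_offset <- 0
  if (!"subject_id" %in% names(df)) df$subject_id <- "s01"
  if (!"session_id" %in% names(df)) df$session_id <- "r01"
  if (n > 0) {
    dims <- vapply(df$signal, dim, integer(2))
    if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
      abort_bad_arg("All epochs in an epoch_set must share the same shape.")
    }
  }
  keep <- c("epoch_id", "source_id", "subject_id", "session_id", "label",
            "start_offset", "augmented", "signal")
  df <- df[, c(intersect(keep, names(df)), setdiff(names(df), keep))]
  attr(df, "sampling_rate") <- sampling_rate
  attr(df, "window") <- window
  class(df) <- unique(c("epoch_set", class(df)))
  df
}

#' @rdname new_epoch_set
#' @param es An `epoch_set`.
#' @export
epoch_sampling_rate <- function(es) {
  r <- attr(es, "sampling_rate")
  if (is.null(r)) abort_bad_arg("epoch_set has no sampling_rate attribute.")
  r
}

# carry epoch_set attributes across dplyr-style row operations
restore_epoch_set <- function(df, template) {
  new_epoch_set(df, attr(template, "sampling_rate"), attr(template, "window"))
}

#' @export
print.epoch_set <- function(x, ...) {
  dims <- if (nrow(x) > 0) dim(x$signal[[1]]) else c(0L, 0L)
  cat(sprintf("<epoch_set> %d epochs (%d augmented), %d ch x %d samples @ %g Hz\n",
              nrow(x), sum(x$augmented), dims[1], dims[2],
              attr(x, "sampling_rate") %||% NA))
  if (nrow(x) > 0) print(table(label = x$label))
  invisible(x)
}

# stack the signal list-column into a (ch*samples) x n matrix for fast math
epochs_as_matrix <- function(es) {
  n <- nrow(es)
  d <- dim(es$signal[[1]])
  out <- matrix(0, d[1] * d[2], n)
  for (i in seq_len(n)) out[, i] <- as.vector(es$signal[[i]])
  out
}
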