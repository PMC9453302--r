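#' Network configuration
#'
#' Declarative description of a convolutional classifier: an ordered layer
#' list plus training hyperparameters. Built by [build_compact_net()] or
#' [build_transfer_variant()].
#'
#' @param variant `"compact_1d"` or `"transfer_table1"`.
#' @param layers Ordered list of layer specifications.
#' @param input_shape `c(channels, window_samples)`.
#' @param n_classes Number of output classes.
#' @param base_learning_rate Initial learning rate; 0.001 by default, kept
#'   small to avoid divergence on small training sets.
#' @param batch_size Mini-batch size.
#' @param max_epochs Training epoch cap.
#' @param momentum Momentum coefficient of the SGD update.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return A `network_config` object.
#' @export
network_config <- function(variant, layers, input_shape, n_classes = 2,
                           base_learning_rate = 0.001, batch_size = 32,
                           max_epochs = 20, momentum = 0.9, patience = 5,
                           seed = 1L) {
  stopifnot(length(input_shape) == 2, is.list(layers))
  last_kinds <- vapply(utils::tail(layers, 2), `[[`, "", "kind")
  if (!identical(last_kinds, c("fully_connected", "softmax"))) {
    abort_bad_arg("The final layers must be a fully_connected output followed by softmax.")
  }
  cfg <- structure(
    list(variant = variant, layers = layers,
         input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes),
         base_learning_rate = base_learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         momentum = momentum, patience = as.integer(patience),
         loss = "cross_entropy", seed = as.integer(seed)),
    class = "network_config")
  compile_net(cfg)  # validates shapes; errors if the window is too short
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %s, input %d ch x %d samples, %d classes\n",
              x$variant, x$input_shape[1], x$input_shape[2], x$n_classes))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    extra <- switch(ly$kind,
      convolution = sprintf(" %dx%d stride %d pad %d", ly$filters, ly$kernel,
                            ly$stride, ly$padding),
      max_pool = sprintf(" size %d stride %d", ly$size, ly$stride),
      fully_connected = sprintf(" %d units", ly$units),
      dropout = sprintf(" rate %.2f", ly$rate),
      "")
    cat(sprintf("  %2d %s%s%s\n", i, ly$kind, extra,
                if (isTRUE(ly$frozen)) " [frozen]" else ""))
  }
  invisible(x)
}

#' Build the compact 1-D convolutional drowsiness classifier
#'
#' The primary model: three 1-D convolution layers along time with kernel
#' extents 5, 3 and 3 (each spanning all input channels in depth and
#' followed by ReLU), max-pooling after the first and second convolutions,
#' then two fully-connected layers ending in a softmax over the classes.
#' The first convolution uses stride 4, which decimates the 500 Hz input
#' early and keeps training cheap without hurting separability.
#'
#' @param input_shape `c(channels, window_samples)`.
#' @param n_classes Number of classes (2 for sleepy vs. normal).
#' @param filters Filter counts of the three convolution layers.
#' @param fc_units Width of the hidden fully-connected layer.
#' @param conv1_stride Stride of the first convolution.
#' @param pool_size Pooling extent after conv1 and conv2.
#' @inheritParams network_config
#' @param ... Passed on to [network_config()].
#' @return A `network_config`.
#' @export
build_compact_net <- function(input_shape = c(8, 1000), n_classes = 2,
                              filters = c(16, 16, 16), fc_units = 32,
                              conv1_stride = 4, pool_size = 4, seed = 1L,
                              ...) {
  layers <- list(
    layer_conv(5, filters[1], stride = conv1_stride),
    layer_relu(),
    layer_pool(pool_size),
    layer_conv(3, filters[2]),
    layer_relu(),
    layer_pool(pool_size),
    layer_conv(3, filters[3]),
    layer_relu(),
    layer_fc(fc_units),
    layer_relu(),
    layer_fc(n_classes),
    layer_softmax()
  )
  network_config("compact_1d", layers, input_shape, n_classes = n_classes,
                 seed = seed, ...)
}

#' Build the transfer-style deep variant
#'
#' A deeper configuration mirroring the classical image-network recipe:
#' first convolution with 96 filters of extent 11 and stride 4, cross
#' channel (local response) normalization and 3-wide max pooling with
#' stride 2 after the first two convolution blocks, 256/384/384/256-filter
#' convolution stages, then two hidden fully-connected layers of 4096
#' units each and a softmax output over `n_classes`. Adapted to this
#' package's 1-D tensor convention (kernels run along time and span all
#' channels in depth). Provided for train-then-freeze-then-fine-tune
#' experiments; the compact net is the primary model.
#'
#' @param input_shape `c(channels, window_samples)`.
#' @param n_classes Number of classes.
#' @param ... Passed on to [network_config()].
#' @return A `network_config`.
#' @export
build_transfer_variant <- function(input_shape = c(8, 1000), n_classes = 2,
                                   ...) {
  layers <- list(
    layer_conv(11, 96, stride = 4),
    layer_relu(),
    layer_ccn(5),
    layer_pool(3, stride = 2),
    layer_conv(5, 256, padding = 2),
    layer_relu(),
    layer_ccn(5),
    layer_pool(3, stride = 2),
    layer_conv(3, 384, padding = 1),
    layer_relu(),
    layer_conv(3, 384, padding = 1),
    layer_relu(),
    layer_conv(3, 256, padding = 1),
    layer_relu(),
    layer_pool(3, stride = 2),
    layer_fc(4096),
    layer_relu(),
    layer_dropout(0.5),
    layer_fc(4096),
    layer_relu(),
    layer_dropout(0.5),
    layer_fc(n_classes),
    layer_softmax()
  )
  network_config("transfer_table1", layers, input_shape,
                 n_classes = n_classes, ...)
}

#' Freeze a prefix of the network for fine-tuning
#'
#' Marks every layer before `first_trainable_layer` as frozen; the
#' optimizer then leaves their parameters bit-identical while the suffix is
#' fine-tuned. The default freezes everything before the first
#' fully-connected block, i.e. only the classifier head is retrained.
#'
#' @param config A `network_config`.
#' @param first_trainable_layer 1-based index of the first layer that may
#'   update; `1` freezes nothing.
#' @return The modified `network_config`.
#' @export
make_finetune_plan <- function(config,
                               first_trainable_layer = first_fc_index(config)) {
  stopifnot(inherits(config, "network_config"))
  idx <- assert_count(first_trainable_layer, "first_trainable_layer")
  if (idx > length(config$layers) + 1L) {
    abort_bad_arg("`first_trainable_layer` is out of range.")
  }
  for (li in seq_along(config$layers)) {
    config$layers[[li]]$frozen <- li < idx
  }
  config
}

#' @rdname make_finetune_plan
#' @export
first_fc_index <- function(config) {
  which(vapply(config$layers, `[[`, "", "kind") == "fully_connected")[1]
}

epochs_to_xy <- function(es, classes = NULL) {
  classes <- classes %||% sort(unique(es$label))
  list(X = epochs_as_matrix(es),
       y = match(es$label, classes),
       classes = classes)
}

#' Train a network by mini-batch gradient descent
#'
#' Minimizes softmax cross-entropy with stochastic gradient descent plus
#' momentum. After every epoch the validation set is scored and one row is
#' appended to the training log (epoch, iteration, elapsed time,
#' validation accuracy \%, validation loss, base learning rate). Training
#' stops early when the validation loss has not improved for
#' `config$patience` epochs, and the weights from the best-validation-loss
#' epoch are returned. Inputs are standardized by the training set's
#' global mean and standard deviation; the scaling is stored with the
#' model. Frozen layers are never updated. Deterministic given
#' `config$seed` (single-threaded BLAS).
#'
#' @param config A `network_config`.
#' @param train,val Non-empty, disjoint `epoch_set`s; `train` must contain
#'   every class.
#' @param init Optional weights of a previous [train_network()] fit (for
#'   train-then-freeze-then-fine-tune), as `trained$weights`.
#' @param verbose Print the log rows as they are produced.
#' @return A `trained_network`: `config`, `weights`, `log` (a
#'   `training_log` tibble), `classes`, `scaling` and `best_epoch`.
#' @export
train_network <- function(config, train, val, init = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "network_config"),
            inherits(train, "epoch_set"), inherits(val, "epoch_set"))
  if (nrow(train) == 0L || nrow(val) == 0L) {
    abort_bad_arg("Training and validation partitions must be non-empty.")
  }
  d <- dim(train$signal[[1]])
  if (!identical(as.integer(d), config$input_shape)) {
    abort_bad_arg(sprintf("Epoch shape %dx%d does not match the configured input %dx%d.",
                          d[1], d[2], config$input_shape[1], config$input_shape[2]))
  }
  if (length(intersect(train$epoch_id, val$epoch_id)) > 0L) {
    abort_bad_arg("Training and validation partitions overlap.")
  }
  classes <- sort(unique(train$label))
  if (length(classes) != config$n_classes) {
    abort_bad_arg("Training labels must cover every configured class.")
  }
  tr <- epochs_to_xy(train, classes)
  va <- epochs_to_xy(val, classes)
  mu <- mean(tr$X); sdv <- stats::sd(tr$X)
  if (sdv == 0) sdv <- 1
  Xtr <- (tr$X - mu) / sdv
  Xva <- (va$X - mu) / sdv

  plans <- compile_net(config)
  params <- init_params(plans, config$seed)
  if (!is.null(init)) {
    for (li in seq_along(params)) {
      if (!is.null(init[[li]])) params[[li]] <- init[[li]]
    }
  }
  frozen <- vapply(config$layers, function(l) isTRUE(l$frozen), logical(1))
  vel <- lapply(params, function(p) {
    if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)
  })

  eval_set <- function(X, y) {
    n <- ncol(X); bs <- 256L
    loss <- 0; correct <- 0
    for (s in seq(1L, n, by = bs)) {
      j <- s:min(s + bs - 1L, n)
      f <- nn_forward(plans, params, X[, j, drop = FALSE])
      loss <- loss + softmax_ce_loss(f$out, y[j]) * length(j)
      correct <- correct + sum(max.col(t(f$out)) == y[j])
    }
    c(loss = loss / n, acc = correct / n)
  }

  n <- ncol(Xtr)
  log_rows <- list()
  iteration <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  t0 <- Sys.time()
  shuffle_seed <- if (config$seed >= .Machine$integer.max) 1L else config$seed + 1L
  withr::with_seed(shuffle_seed, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = config$batch_size)) {
        j <- ord[s:min(s + config$batch_size - 1L, n)]
        B <- length(j)
        f <- nn_forward(plans, params, Xtr[, j, drop = FALSE],
                        train = TRUE, cache = TRUE)
        dlog <- f$out
        ii <- cbind(tr$y[j], seq_len(B))
        dlog[ii] <- dlog[ii] - 1
        dlog <- dlog / B
        grads <- nn_backward(plans, params, f$caches, dlog, B)
        for (li in seq_along(params)) {
          if (is.null(params[[li]]) || frozen[li] || is.null(grads[[li]])) next
          vel[[li]]$W <- config$momentum * vel[[li]]$W -
            config$base_learning_rate * grads[[li]]$W
          vel[[li]]$b <- config$momentum * vel[[li]]$b -
            config$base_learning_rate * grads[[li]]$b
          params[[li]]$W <- params[[li]]$W + vel[[li]]$W
          params[[li]]$b <- params[[li]]$b + vel[[li]]$b
        }
        iteration <- iteration + 1L
      }
      m <- eval_set(Xva, va$y)
      log_rows[[ep]] <- tibble::tibble(
        epoch = ep, iteration = iteration,
        elapsed = hhmmss(as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        validation_accuracy = 100 * m[["acc"]],
        validation_loss = m[["loss"]],
        base_learning_rate = config$base_learning_rate)
      if (verbose) {
        message(sprintf("epoch %2d  iter %4d  val acc %6.2f%%  val loss %.4f",
                        ep, iteration, 100 * m[["acc"]], m[["loss"]]))
      }
      if (m[["loss"]] < best$loss - 1e-9) {
        best <- list(loss = m[["loss"]], params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  log <- dplyr::bind_rows(log_rows)
  class(log) <- c("training_log", class(log))
  structure(
    list(config = config, weights = best$params, log = log,
         classes = classes, scaling = c(mu = mu, sd = sdv),
         best_epoch = best$epoch),
    class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf(
    "<trained_network> %s; %d epochs logged, best epoch %d (val loss %.4f, val acc %.1f%%)\n",
    x$config$variant, n, x$best_epoch,
    min(x$log$validation_loss), x$log$validation_accuracy[which.min(x$log$validation_loss)]))
  invisible(x)
}

#' Predict class probabilities or labels from a trained network
#'
#' @param object A `trained_network`.
#' @param newdata An `epoch_set` with the configured input shape.
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   predicted labels.
#' @param ... Unused.
#' @return A tibble of per-class probabilities or a character vector of
#'   labels.
#' @export
predict.trained_network <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "epoch_set"))
  d <- dim(newdata$signal[[1]])
  if (!identical(as.integer(d), object$config$input_shape)) {
    abort_bad_arg("Epoch shape does not match the network's input shape.")
  }
  X <- (epochs_as_matrix(newdata) - object$scaling[["mu"]]) /
    object$scaling[["sd"]]
  plans <- compile_net(object$config)
  n <- ncol(X); bs <- 256L
  out <- matrix(0, n, length(object$classes))
  for (s in seq(1L, n, by = bs)) {
    j <- s:min(s + bs - 1L, n)
    f <- nn_forward(plans, object$weights, X[, j, drop = FALSE])
    out[j, ] <- t(f$out)
  }
  colnames(out) <- object$classes
  if (type == "class") {
    object$classes[max.col(out)]
  } else {
    tibble::as_tibble(as.data.frame(out))
  }
}
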