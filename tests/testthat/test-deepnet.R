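test_that("compact net has the prescribed 3-conv architecture", {
  cfg <- build_compact_net(c(8, 1000))
  kinds <- vapply(cfg$layers, `[[`, "", "kind")
  convs <- which(kinds == "convolution")
  expect_length(convs, 3L)
  expect_equal(vapply(cfg$layers[convs], `[[`, integer(1), "kernel"),
               c(5L, 3L, 3L))
  # ReLU follows every convolution
  expect_true(all(kinds[convs + 1L] == "relu"))
  # pooling after conv1 and conv2 blocks, none after conv3
  expect_equal(sum(kinds == "max_pool"), 2L)
  expect_true(all(which(kinds == "max_pool") < convs[3]))
  # two fully-connected layers, then softmax
  expect_equal(sum(kinds == "fully_connected"), 2L)
  expect_equal(utils::tail(kinds, 2), c("fully_connected", "softmax"))
  expect_equal(cfg$layers[[which(kinds == "fully_connected")[2]]]$units, 2L)
  expect_equal(cfg$base_learning_rate, 0.001)
})

test_that("forward pass of the compact net is a probability over classes", {
  cfg <- build_compact_net(c(4, 300), seed = 2)
  plans <- sleepyEEG:::compile_net(cfg)
  params <- sleepyEEG:::init_params(plans, cfg$seed)
  X <- cbind(numeric(4 * 300), rnorm(4 * 300))
  out <- sleepyEEG:::nn_forward(plans, params, X)$out
  expect_equal(colSums(out), c(1, 1), tolerance = 1e-6)
  expect_true(all(out >= 0))
})

test_that("too-short windows are rejected at build time", {
  expect_error(build_compact_net(c(8, 8)), "too short")
})

test_that("transfer variant transcribes the deep recipe", {
  cfg <- build_transfer_variant(c(8, 1000))
  kinds <- vapply(cfg$layers, `[[`, "", "kind")
  fcs <- which(kinds == "fully_connected")
  expect_length(fcs, 3L)
  expect_equal(vapply(cfg$layers[fcs[1:2]], `[[`, integer(1), "units"),
               c(4096L, 4096L))
  conv1 <- cfg$layers[[which(kinds == "convolution")[1]]]
  expect_equal(conv1$stride, 4L)
  expect_equal(conv1$filters, 96L)
  pools <- cfg$layers[kinds == "max_pool"]
  expect_true(all(vapply(pools, `[[`, integer(1), "size") == 3L))
  expect_true(all(vapply(pools, `[[`, integer(1), "stride") == 2L))
  expect_equal(sum(kinds == "cross_channel_norm"), 2L)
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- build_compact_net(c(2, 60), filters = c(3, 3, 3), fc_units = 4,
                           conv1_stride = 2, pool_size = 2, seed = 5)
  plans <- sleepyEEG:::compile_net(cfg)
  params <- sleepyEEG:::init_params(plans, cfg$seed)
  withr::with_seed(8, {
    X <- matrix(rnorm(2 * 60 * 3), ncol = 3)
    y <- c(1L, 2L, 1L)
  })
  loss_fn <- function(p) {
    f <- sleepyEEG:::nn_forward(plans, p, X)
    sleepyEEG:::softmax_ce_loss(f$out, y)
  }
  f <- sleepyEEG:::nn_forward(plans, params, X, cache = TRUE)
  dlog <- f$out
  ii <- cbind(y, seq_along(y))
  dlog[ii] <- dlog[ii] - 1
  dlog <- dlog / length(y)
  grads <- sleepyEEG:::nn_backward(plans, params, f$caches, dlog, length(y))

  eps <- 1e-5
  for (li in which(!vapply(grads, is.null, logical(1)))) {
    w_idx <- c(1L, length(params[[li]]$W) %/% 2L + 1L, length(params[[li]]$W))
    for (wi in unique(w_idx)) {
      p2 <- params; p2[[li]]$W[wi] <- p2[[li]]$W[wi] + eps
      p3 <- params; p3[[li]]$W[wi] <- p3[[li]]$W[wi] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(grads[[li]]$W[wi], num, tolerance = 1e-4)
    }
    b2 <- params; b2[[li]]$b[1] <- b2[[li]]$b[1] + eps
    b3 <- params; b3[[li]]$b[1] <- b3[[li]]$b[1] - eps
    num_b <- (loss_fn(b2) - loss_fn(b3)) / (2 * eps)
    expect_equal(grads[[li]]$b[1], num_b, tolerance = 1e-4)
  }
})

test_that("cross-channel normalization gradients are exact too", {
  layers <- list(sleepyEEG:::layer_conv(3, 4), sleepyEEG:::layer_ccn(3),
                 sleepyEEG:::layer_relu(), sleepyEEG:::layer_fc(2),
                 sleepyEEG:::layer_softmax())
  cfg <- structure(list(variant = "t", layers = layers,
                        input_shape = c(2L, 20L), n_classes = 2L, seed = 3L),
                   class = "network_config")
  plans <- sleepyEEG:::compile_net(cfg)
  params <- sleepyEEG:::init_params(plans, 3L)
  withr::with_seed(4, X <- matrix(rnorm(2 * 20 * 2), ncol = 2))
  y <- c(2L, 1L)
  loss_fn <- function(p) {
    sleepyEEG:::softmax_ce_loss(sleepyEEG:::nn_forward(plans, p, X)$out, y)
  }
  f <- sleepyEEG:::nn_forward(plans, params, X, cache = TRUE)
  dlog <- f$out; ii <- cbind(y, 1:2); dlog[ii] <- dlog[ii] - 1; dlog <- dlog / 2
  grads <- sleepyEEG:::nn_backward(plans, params, f$caches, dlog, 2L)
  eps <- 1e-5
  for (wi in c(1L, 7L)) {
    p2 <- params; p2[[1]]$W[wi] <- p2[[1]]$W[wi] + eps
    p3 <- params; p3[[1]]$W[wi] <- p3[[1]]$W[wi] - eps
    expect_equal(grads[[1]]$W[wi], (loss_fn(p2) - loss_fn(p3)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("fine-tune plans freeze the right layers and freezing holds", {
  cfg <- build_compact_net(c(2, 100), filters = c(2, 2, 2), fc_units = 4,
                           conv1_stride = 2, pool_size = 2,
                           max_epochs = 2, batch_size = 8, seed = 6)
  none <- make_finetune_plan(cfg, 1)
  expect_false(any(vapply(none$layers, `[[`, logical(1), "frozen")))

  tcfg <- build_transfer_variant(c(8, 1000))
  plan <- make_finetune_plan(tcfg)
  kinds <- vapply(plan$layers, `[[`, "", "kind")
  first_fc <- which(kinds == "fully_connected")[1]
  frozen <- vapply(plan$layers, `[[`, logical(1), "frozen")
  expect_true(all(frozen[seq_len(first_fc - 1)]))
  expect_false(any(frozen[first_fc:length(frozen)]))
  expect_error(make_finetune_plan(cfg, 99), "range")

  # frozen prefix stays bit-identical through training; suffix moves
  es <- toy_band_epochs(n_per_class = 20, nch = 2, n = 100)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.25, seed = 1))
  base <- train_network(cfg, sp$train, sp$heldout)
  part <- make_finetune_plan(cfg, first_fc_index(cfg))
  tuned <- train_network(part, sp$train, sp$heldout, init = base$weights)
  for (li in seq_along(part$layers)) {
    if (is.null(base$weights[[li]])) next
    if (part$layers[[li]]$frozen) {
      expect_identical(tuned$weights[[li]]$W, base$weights[[li]]$W)
      expect_identical(tuned$weights[[li]]$b, base$weights[[li]]$b)
    }
  }
  moved <- vapply(seq_along(part$layers), function(li) {
    !is.null(base$weights[[li]]) && !part$layers[[li]]$frozen &&
      !identical(tuned$weights[[li]]$W, base$weights[[li]]$W)
  }, logical(1))
  expect_true(any(moved))
})

test_that("freezing every layer leaves the network untouched", {
  cfg <- build_compact_net(c(2, 100), filters = c(2, 2, 2), fc_units = 4,
                           conv1_stride = 2, pool_size = 2,
                           max_epochs = 3, batch_size = 8, seed = 9)
  all_frozen <- make_finetune_plan(cfg, length(cfg$layers) + 1L)
  es <- toy_band_epochs(n_per_class = 12, nch = 2, n = 100)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.25, seed = 2))
  base <- train_network(cfg, sp$train, sp$heldout)
  ref <- train_network(all_frozen, sp$train, sp$heldout, init = base$weights)
  for (li in seq_along(cfg$layers)) {
    if (is.null(base$weights[[li]])) next
    expect_identical(ref$weights[[li]]$W, base$weights[[li]]$W)
  }
  # with no parameter updates the validation metrics cannot change
  expect_equal(length(unique(ref$log$validation_loss)), 1L)
  expect_equal(length(unique(ref$log$validation_accuracy)), 1L)
})

test_that("training is reproducible and bookkeeping is consistent", {
  cfg <- build_compact_net(c(2, 100), filters = c(4, 4, 4), fc_units = 8,
                           conv1_stride = 2, pool_size = 2,
                           max_epochs = 4, batch_size = 16, seed = 21)
  es <- toy_band_epochs(n_per_class = 30, nch = 2, n = 100)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.2, seed = 3))
  a <- train_network(cfg, sp$train, sp$heldout)
  b <- train_network(cfg, sp$train, sp$heldout)
  expect_identical(a$log$validation_loss, b$log$validation_loss)
  expect_identical(a$log$validation_accuracy, b$log$validation_accuracy)
  # iterations strictly increase; best epoch attains the minimum loss
  expect_true(all(diff(a$log$iteration) > 0))
  expect_equal(min(a$log$validation_loss),
               a$log$validation_loss[a$best_epoch])
  expect_true(all(a$log$validation_accuracy >= 0 &
                    a$log$validation_accuracy <= 100))
})

test_that("the compact net learns a separable band-power contrast", {
  es <- toy_band_epochs(n_per_class = 150, nch = 2, n = 250)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.2, seed = 4))
  cfg <- build_compact_net(c(2, 250), max_epochs = 12, seed = 31,
                           conv1_stride = 2)
  fit <- train_network(cfg, sp$train, sp$heldout)
  acc <- max(fit$log$validation_accuracy)
  expect_gt(acc, 85)
  # loss falls and accuracy rises over training on separable data
  expect_lt(min(fit$log$validation_loss), fit$log$validation_loss[1])
  pred <- predict(fit, sp$heldout, type = "class")
  expect_gt(mean(pred == sp$heldout$label), 0.8)
})

test_that("train_network rejects malformed partitions", {
  es <- toy_band_epochs(n_per_class = 10, nch = 2, n = 100)
  cfg <- build_compact_net(c(2, 100), filters = c(2, 2, 2), fc_units = 4,
                           conv1_stride = 2, pool_size = 2)
  sp <- holdout_split(es, split_spec("holdout", test_fraction = 0.3, seed = 1))
  expect_error(train_network(cfg, sp$train, sp$train), "overlap")
  empty <- new_epoch_set(es[0, ], 500, attr(es, "window"))
  expect_error(train_network(cfg, sp$train, empty), "non-empty")
  wrong <- toy_band_epochs(n_per_class = 4, nch = 2, n = 50)
  expect_error(train_network(cfg, wrong, sp$heldout), "shape|match")
})
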