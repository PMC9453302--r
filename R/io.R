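#' Write a recording as CSV plus JSON sidecar
#'
#' The signal goes to `<path>` as CSV - one row per sample, one column per
#' channel, header = channel names, values in microvolts printed with six
#' fixed decimal places so the byte output is deterministic. Metadata
#' (sampling rate, identifiers, label, channel names, sample count and
#' optional seed provenance) goes to the sidecar `<path with .json>`.
#'
#' @param rec An [eeg_recording()].
#' @param path Destination CSV path.
#' @param seed Optional integer recorded as provenance in the sidecar.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, path, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0L) abort_bad_arg("Refusing to write an empty recording.")
  fmt <- sprintf("%.6f", t(rec$data))
  dim(fmt) <- c(ncol(rec$data), nrow(rec$data))
  lines <- c(paste(rec$channel_names, collapse = ","),
             do.call(paste, c(lapply(seq_len(ncol(fmt)), function(j) fmt[, j]),
                              sep = ",")))
  writeLines(lines, path)
  sidecar <- sidecar_path(path)
  meta <- list(
    sampling_rate = rec$sampling_rate,
    subject_id = rec$subject_id,
    session_id = rec$session_id,
    label = rec$label,
    channel_names = rec$channel_names,
    n_samples = ncol(rec$data)
  )
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, sidecar))
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a recording written by [write_recording()]
#'
#' Round-trips losslessly to the six decimal places the writer emits.
#' Fails loudly on a missing sidecar, disagreeing channel counts or
#' non-finite values.
#'
#' @param path CSV path (the sidecar is found next to it).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(path)) abort_bad_arg(sprintf("Signal file '%s' not found.", path))
  if (!file.exists(sidecar)) {
    abort_bad_arg(sprintf("Sidecar '%s' is missing.", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) != length(meta$channel_names)) {
    abort_bad_arg(sprintf(
      "Channel count mismatch: CSV has %d columns but the sidecar lists %d channels.",
      ncol(df), length(meta$channel_names)))
  }
  m <- t(as.matrix(df))
  if (anyNA(m) || !all(is.finite(m))) {
    abort_bad_arg("Signal file contains missing or non-finite values.")
  }
  eeg_recording(m, meta$sampling_rate, subject_id = meta$subject_id,
                session_id = meta$session_id, label = meta$label,
                channel_names = meta$channel_names)
}

#' @describeIn read_recording Write every recording of an `eeg_dataset`
#'   into a directory (`<subject>_<session>.csv` + sidecars).
#' @param dataset An `eeg_dataset`.
#' @param dir Destination directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- attr(dataset, "seed")
  paths <- vapply(dataset$recording, function(rec) {
    p <- file.path(dir, sprintf("%s_%s.csv", rec$subject_id, rec$session_id))
    write_recording(rec, p, seed = seed)
    p
  }, character(1))
  invisible(paths)
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)

config_schema <- function() {
  list(
    seed = NULL,
    protocol = c("n_subjects", "n_sessions_per_subject", "session_duration",
                 "n_trials_per_session", "sampling_rate", "n_channels"),
    sources = c("sleepy_alpha", "sleepy_beta", "normal_alpha", "normal_beta",
                "background_sd", "sensor_noise_sd"),
    filter = c("low_cut", "high_cut", "order", "zero_phase"),
    segmentation = c("window", "overlap_fraction", "amplitude_limit"),
    augment = c("mu", "sigma", "copies_per_epoch", "mode"),
    features = c("n_csp", "log_bp"),
    network = c("enabled", "max_epochs", "batch_size", "base_learning_rate",
                "filters", "fc_units", "patience"),
    evaluation = c("kind", "test_fraction", "k", "shuffle",
                   "positive_threshold", "baselines")
  )
}

#' Read and validate a pipeline run configuration
#'
#' The YAML document may contain the sections `protocol`, `sources`,
#' `filter`, `segmentation`, `augment`, `features`, `network` and
#' `evaluation` plus a global `seed`; unknown sections or keys are
#' rejected so typos cannot silently fall back to defaults. Every value
#' defaults to the package defaults documented on the corresponding
#' constructor.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0) {
    abort_bad_arg(sprintf("Unknown config section(s): %s.",
                          paste(unknown, collapse = ", ")))
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad) > 0) {
      abort_bad_arg(sprintf("Unknown key(s) in section '%s': %s.",
                            sec, paste(bad, collapse = ", ")))
    }
  }
  defaults <- list(
    seed = 1L,
    protocol = list(n_subjects = 20, n_sessions_per_subject = 3,
                    session_duration = 420, n_trials_per_session = 40,
                    sampling_rate = 500, n_channels = 8),
    sources = list(sleepy_alpha = 15, sleepy_beta = 5,
                   normal_alpha = 15 / sqrt(3), normal_beta = 12,
                   background_sd = 2, sensor_noise_sd = 1),
    filter = list(low_cut = 1, high_cut = 30, order = 5, zero_phase = TRUE),
    segmentation = list(window = 2, overlap_fraction = 0, amplitude_limit = 100),
    augment = list(mu = 1, sigma = 0.1, copies_per_epoch = 2,
                   mode = "per_sample"),
    features = list(n_csp = 4, log_bp = TRUE),
    network = list(enabled = TRUE, max_epochs = 20, batch_size = 32,
                   base_learning_rate = 0.001, filters = c(16, 16, 16),
                   fc_units = 32, patience = 5),
    evaluation = list(kind = "holdout", test_fraction = 0.2, k = 10,
                      shuffle = TRUE, positive_threshold = 0.5,
                      baselines = TRUE)
  )
  out <- defaults
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  for (sec in setdiff(names(cfg), "seed")) {
    out[[sec]] <- utils::modifyList(defaults[[sec]], cfg[[sec]])
  }
  if (out$evaluation$kind == "kfold" && out$evaluation$k < 2) {
    abort_bad_arg("evaluation.k must be >= 2 for k-fold evaluation.")
  }
  structure(out, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "sleepyEEG_stage_error", parent = e)
  })
}

#' Execute the full simulation-to-report pipeline
#'
#' Runs simulate, filter, segment, artifact rejection, holdout split,
#' training-side augmentation, classical baselines and/or compact-CNN
#' training, and final evaluation, writing every artifact into `out_dir`:
#' `manifest.json` (the fully-resolved config, seeds and stage counts),
#' `training_log.csv`, `eval_report.csv`, `roc.csv` and
#' `baseline_table.csv`. The held-out 20% is divided evenly into a
#' validation half (early stopping) and a test half (reported metrics).
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out_dir Output directory, created if needed.
#' @param verbose Print stage progress.
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- list()

  dataset <- stage("simulate", {
    pr <- config$protocol
    protocol <- session_protocol(pr$n_subjects, pr$n_sessions_per_subject,
                                 pr$session_duration, pr$n_trials_per_session,
                                 pr$sampling_rate, pr$n_channels)
    so <- config$sources
    generate_dataset(
      protocol,
      sleepy_spec = source_spec("sleepy",
        default_band_table(alpha = so$sleepy_alpha, beta = so$sleepy_beta),
        background_sd = so$background_sd),
      normal_spec = source_spec("normal",
        default_band_table(alpha = so$normal_alpha, beta = so$normal_beta),
        background_sd = so$background_sd),
      model = default_mixing_model(pr$n_channels,
                                   sensor_noise_sd = so$sensor_noise_sd,
                                   seed = config$seed),
      seed = config$seed)
  })
  counts$recordings <- nrow(dataset)
  say("simulate: %d recordings", counts$recordings)

  dataset <- stage("filter", {
    fl <- config$filter
    bandpass_dataset(dataset, filter_spec(fl$low_cut, fl$high_cut, fl$order,
                                          fl$zero_phase))
  })

  epochs <- stage("segment", {
    sg <- config$segmentation
    zero_center_epochs(segment_dataset(dataset, sg$window, sg$overlap_fraction))
  })
  counts$epochs <- nrow(epochs)
  say("segment: %d epochs", counts$epochs)

  epochs <- stage("reject", {
    reject_artifacts(epochs, config$segmentation$amplitude_limit)
  })
  counts$epochs_clean <- nrow(epochs)

  seeds <- derive_seeds(config$seed, 4L)
  sp <- stage("split", {
    holdout_split(epochs, split_spec("holdout",
      test_fraction = config$evaluation$test_fraction, seed = seeds[1]))
  })
  held <- stage("split", {
    holdout_split(sp$heldout, split_spec("holdout", test_fraction = 0.5,
                                         seed = seeds[2]))
  })
  val <- held$heldout; test <- held$train
  counts$train <- nrow(sp$train); counts$val <- nrow(val); counts$test <- nrow(test)

  train <- stage("augment", {
    au <- config$augment
    augment_epochset(sp$train, augment_spec(au$mu, au$sigma,
                                            au$copies_per_epoch,
                                            seed = seeds[3], mode = au$mode))
  })
  counts$train_augmented <- nrow(train)
  say("augment: %d -> %d training epochs", counts$train, counts$train_augmented)

  baseline_table <- NULL
  if (isTRUE(config$evaluation$baselines)) {
    baseline_table <- stage("baselines", {
      csp <- fit_csp(train, n_components = config$features$n_csp)
      pool <- restore_epoch_set(
        dplyr::bind_rows(tibble::as_tibble(train), tibble::as_tibble(test)),
        train)
      bp <- bp_features(pool, log = config$features$log_bp)
      cf <- apply_csp(csp, pool)
      fsets <- list(BP = bp, CSP = cf, `BP+CSP` = concat_features(bp, cf))
      ntr <- nrow(train)
      split_fixed <- list(list(train = seq_len(ntr),
                               test = ntr + seq_len(nrow(test))))
      col_name <- c(tree = "Tree", lda = "LDA", svm = "SVM", knn = "KNN")
      out <- tibble::tibble(feature_set = names(fsets))
      for (cl in names(col_name)) {
        out[[col_name[[cl]]]] <- vapply(fsets, function(fm) {
          fitted <- fit_classifier(fm[split_fixed[[1]]$train, ], cl)
          sc <- score_classifier(fitted, fm[split_fixed[[1]]$test, ])
          te <- fm[split_fixed[[1]]$test, ]
          mean((sc >= 0.5) == (te$label == fitted$positive))
        }, numeric(1))
      }
      out
    })
    readr::write_csv(baseline_table, file.path(out_dir, "baseline_table.csv"))
    say("baselines written")
  }

  report <- NULL; net <- NULL
  if (isTRUE(config$network$enabled)) {
    net <- stage("train_cnn", {
      nw <- config$network
      cfg <- build_compact_net(dim(train$signal[[1]]),
                               filters = nw$filters, fc_units = nw$fc_units,
                               max_epochs = nw$max_epochs,
                               batch_size = nw$batch_size,
                               base_learning_rate = nw$base_learning_rate,
                               patience = nw$patience, seed = seeds[4])
      train_network(cfg, train, val, verbose = verbose)
    })
    log_df <- tibble::as_tibble(net$log)
    names(log_df) <- c("Epoch", "Iteration", "Time elapsed HH:MM:SS",
                       "Validation accuracy (%)", "Validation loss",
                       "Base learning rate")
    readr::write_csv(log_df, file.path(out_dir, "training_log.csv"))
    report <- stage("evaluate", {
      pos <- if ("sleepy" %in% net$classes) "sleepy" else net$classes[1]
      scores <- predict(net, test, type = "prob")[[pos]]
      compute_metrics(test$label, scores,
                      positive_threshold = config$evaluation$positive_threshold,
                      positive = pos)
    })
    readr::write_csv(tidy(report), file.path(out_dir, "eval_report.csv"))
    if (!is.null(report$roc)) {
      readr::write_csv(tibble::as_tibble(report$roc), file.path(out_dir, "roc.csv"))
    }
    say("CNN test accuracy %.3f", report$accuracy)
  }

  manifest <- list(
    config = unclass(config),
    derived_seeds = as.integer(seeds),
    counts = counts,
    accuracy = if (!is.null(report)) report$accuracy else NULL,
    auc = if (!is.null(report)) report$auc else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
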