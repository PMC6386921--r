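# End-to-end orchestration: generate -> train (motion + group bank + flat
# baselines) -> recognize (hierarchical, direct fusion avg/max, flat
# single-modality) -> evaluate, with a machine-readable summary. All
# randomness flows from one experiment seed.

SUMMARY_SCHEMA_VERSION <- 1L

#' Configure an experiment
#'
#' @param spec a [generator_spec()] (e.g. from [preset()]).
#' @param n_train,n_test training and test sample counts.
#' @param train a [train_config()].
#' @param seed experiment seed; dataset and fit seeds are derived from it.
#' @param out_dir optional output directory for confusion CSVs and the
#'   summary JSON.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(spec, n_train = 3000L, n_test = 1500L,
                              train = train_config("ci"), seed = 1L,
                              out_dir = NULL) {
  stopifnot(inherits(spec, "generator_spec"), inherits(train, "train_config"))
  structure(list(spec = spec, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), train = train,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

dataset_parts <- function(ds) {
  list(segments = lapply(ds$samples, `[[`, "segment"),
       payloads = lapply(ds$samples, `[[`, "payload"),
       activity = vapply(ds$samples, `[[`, character(1), "activity"),
       state = vapply(ds$samples, `[[`, character(1), "state"))
}

fit_group_bank <- function(C, regime, payloads, activity, config, seed) {
  multi <- setdiff(C$states$labels, singleton_groups(C))
  bank <- list()
  for (s in multi) {
    acts <- group_activities(C, s)
    # multi-state activities contribute their frames to every group they
    # belong to
    idx <- which(activity %in% acts)
    bank[[s]] <- if (regime == "low")
      fit_group_frame_classifier(acts, payloads[idx], activity[idx],
                                 config = config, seed = seed)
    else
      fit_group_sequence_classifier(acts, payloads[idx], activity[idx],
                                    config = config, seed = seed)
    seed <- seed + 1L
  }
  bank
}

#' Run a full recognition experiment on synthetic data
#'
#' Generates train/test datasets from the spec, trains the motion-state
#' classifier, the per-group image bank, and the two flat single-modality
#' baselines, then scores five methods on the same test set: hierarchical,
#' sensor-only flat, image-only flat, and direct fusion of the flat
#' posteriors by average and by maximum pooling.
#'
#' @param config an [experiment_config()].
#' @return object of class `experiment_result`: list with `reports` (named
#'   list of [f1_report()] objects), `confusions`, `comparison`
#'   (data.frame of macro-F1/accuracy per method), `summary` (plain list,
#'   schema-versioned), and the fitted `bundle`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- config$spec
  C <- spec$C
  A_labels <- C$activities$labels
  seed <- config$seed
  train_ds <- generate_dataset(spec, config$n_train, seed = seed)
  test_ds <- generate_dataset(spec, config$n_test, seed = seed + 1L)
  tr <- dataset_parts(train_ds); te <- dataset_parts(test_ds)
  cfg <- config$train

  motion <- fit_motion_classifier(tr$segments, tr$state, C$states,
                                  config = cfg, seed = seed + 10L)
  flat_sensor <- fit_motion_classifier(tr$segments, tr$activity,
                                       motion_state_set(A_labels),
                                       config = cfg, seed = seed + 11L)
  bank <- fit_group_bank(C, spec$regime, tr$payloads, tr$activity,
                         cfg, seed + 20L)
  # in a one-group hierarchy the flat image classifier and the single group
  # model are one and the same object
  flat_image <- if (C$states$m == 1L && length(bank) == 1L)
    bank[[1L]]
  else if (spec$regime == "low")
    fit_group_frame_classifier(A_labels, tr$payloads, tr$activity,
                               config = cfg, seed = seed + 12L)
  else
    fit_group_sequence_classifier(A_labels, tr$payloads, tr$activity,
                                  config = cfg, seed = seed + 12L)

  bundle <- hier_recognizer(C, motion, bank,
                            ips = if (spec$regime == "low") "L" else "H")
  samples <- test_ds$samples
  hier_pred <- predict(bundle, samples)$activity
  Ps <- predict(flat_sensor, te$segments)           # sensor posteriors over A
  Pi <- predict(flat_image, te$payloads)            # image posteriors over A
  sensor_pred <- A_labels[apply(Ps, 1L, which.max)]
  image_pred <- A_labels[apply(Pi, 1L, which.max)]
  fuse_pred <- function(mode) {
    A_labels[vapply(seq_len(nrow(Ps)), function(i)
      which.max(direct_fuse(list(Ps[i, ], Pi[i, ]), mode)), integer(1))]
  }
  preds <- list(hierarchical = hier_pred, sensor_only = sensor_pred,
                image_only = image_pred, direct_avg = fuse_pred("avg"),
                direct_max = fuse_pred("max"))
  confusions <- lapply(preds, function(p) confusion_matrix(te$activity, p, A_labels))
  reports <- lapply(confusions, f1_report)
  comparison <- data.frame(
    method = names(reports),
    macro_f1 = vapply(reports, function(r) unname(r$macro["f1"]), numeric(1)),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    row.names = NULL)
  summary <- list(schema_version = SUMMARY_SCHEMA_VERSION,
                  hierarchy_fingerprint = hierarchy_fingerprint(C),
                  regime = spec$regime, seed = config$seed,
                  n_train = config$n_train, n_test = config$n_test,
                  profile = cfg$profile,
                  macro_f1 = as.list(stats::setNames(comparison$macro_f1,
                                                     comparison$method)),
                  accuracy = as.list(stats::setNames(comparison$accuracy,
                                                     comparison$method)))
  res <- structure(list(reports = reports, confusions = confusions,
                        comparison = comparison, summary = summary,
                        bundle = bundle, flat_sensor = flat_sensor,
                        flat_image = flat_image),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(confusions))
      write_confusion_csv(confusions[[nm]],
                          file.path(config$out_dir, paste0("confusion_", nm, ".csv")))
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Recognition experiment (synthetic data)\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep grouping methods
#'
#' Runs the hierarchical pipeline under several packaged groupings of the
#' same activity set and reports, per grouping: motion-layer accuracy, the
#' min and max group image-classifier accuracy, and the fused (hierarchical)
#' accuracy.
#'
#' @param groupings character vector of fixture names sharing one activity
#'   set (default the 20-activity groupings `M5`--`M8`).
#' @param n_train,n_test sample counts per grouping.
#' @param train a [train_config()].
#' @param seed sweep seed.
#' @param ... overrides passed to [generator_spec()] (e.g. `K`, `delta`).
#' @return data.frame with one row per grouping.
#' @export
grouping_sweep <- function(groupings = c("M5", "M6", "M7", "M8"),
                           n_train = 600L, n_test = 400L,
                           train = train_config("ci"), seed = 1L, ...) {
  rows <- lapply(seq_along(groupings), function(gi) {
    C <- load_fixture(groupings[gi])
    spec <- generator_spec(C, regime = "high", ...)
    cfg <- experiment_config(spec, n_train = n_train, n_test = n_test,
                             train = train, seed = seed + 100L * gi)
    res <- run_experiment(cfg)
    test_ds <- generate_dataset(spec, cfg$n_test, seed = cfg$seed + 1L)
    te <- dataset_parts(test_ds)
    mp <- predict(res$bundle$motion_model, te$segments)
    motion_acc <- mean(C$states$labels[apply(mp, 1, which.max)] == te$state)
    multi <- setdiff(C$states$labels, singleton_groups(C))
    img_acc <- vapply(multi, function(s) {
      acts <- group_activities(C, s)
      idx <- which(te$state == s)
      if (!length(idx)) return(NA_real_)
      GP <- predict(res$bundle$group_models[[s]], te$payloads[idx])
      mean(acts[apply(GP, 1, which.max)] == te$activity[idx])
    }, numeric(1))
    data.frame(grouping = groupings[gi], m = C$states$m,
               n_multi_groups = length(multi),
               motion_accuracy = motion_acc,
               image_accuracy_min = min(img_acc, na.rm = TRUE),
               image_accuracy_max = max(img_acc, na.rm = TRUE),
               fused_accuracy = res$reports$hierarchical$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
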