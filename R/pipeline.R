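#' Build a run configuration
#'
#' A single nested configuration object driving the end-to-end pipeline:
#' simulation (or input files), binning grid, augmentation, ensemble,
#' decision rule and split settings, plus one global seed from which every
#' stage's seed is derived. A run is reproducible from its configuration
#' alone.
#'
#' @param seed global integer seed.
#' @param sim named list of [sim_config()] overrides (used when no input
#'   files are given).
#' @param data optional list with `mzml_files` (character vector) and
#'   parallel `labels` (and optionally `batch_ids`) to run on real data
#'   instead of simulated data.
#' @param grid list: `type` (`"uniform"`, `"adaptive"` or `"estimate"`),
#'   `rt_width`/`mz_width` for uniform grids, `regions` (data.frame) for
#'   adaptive grids, `n_regions`/`fine_width`/`broad_width` for estimated
#'   priors. RT width defaults to the scan interval.
#' @param augment list: `enabled`, `max_shift` (s), `copies`.
#' @param model list: `n_members` plus [member_config()] overrides.
#' @param decision list: `threshold` (`"auto"` or a number in `[0, 1]`),
#'   `candidates`, `val_fraction` (fraction of training data used to
#'   select the threshold, default 0.1).
#' @param split list: `test_fraction` (default 0.25).
#' @param scale min-max scaling mode: `"column"`, `"global"` or `"none"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = list(), data = NULL,
                       grid = list(type = "uniform", mz_width = 2),
                       augment = list(enabled = TRUE, max_shift = 10, copies = 1),
                       model = list(n_members = 5),
                       decision = list(threshold = "auto",
                                       candidates = seq(0, 0.95, by = 0.05),
                                       val_fraction = 0.1),
                       split = list(test_fraction = 0.25),
                       scale = "column") {
  cfg <- list(seed = as.integer(seed), sim = sim, data = data, grid = grid,
              augment = augment, model = model, decision = decision,
              split = split, scale = scale)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  required <- c("seed", "grid", "augment", "model", "decision", "split", "scale")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort_lcms(sprintf("run configuration is missing required key(s): %s",
                       paste(missing, collapse = ", ")),
               "lcmsnet_validation_error")
  }
  if (is.null(cfg$grid$type)) {
    abort_lcms("run configuration is missing required key: grid$type",
               "lcmsnet_validation_error")
  }
  thr <- cfg$decision$threshold
  if (!is.null(thr) && !identical(thr, "auto")) check_number(thr, "decision$threshold",
                                                             lower = 0, upper = 1)
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$data <- out$data
  yaml::write_yaml(out, path)
  invisible(path)
}

pipeline_grid <- function(cfg, samples) {
  rt_span <- samples[[1]]$acquisition_span
  rts <- samples[[1]]$points$rt
  scan_interval <- if (!is.null(cfg$sim$scan_interval)) cfg$sim$scan_interval
    else min(diff(sort(unique(rts))))
  g <- cfg$grid
  mz_span <- if (!is.null(cfg$sim$mz_span)) as.numeric(cfg$sim$mz_span) else {
    range(unlist(lapply(samples, function(s) s$points$mz)))
  }
  switch(g$type,
    uniform = build_uniform_grid(
      rt_span, if (!is.null(g$rt_width)) g$rt_width else scan_interval,
      mz_span, if (!is.null(g$mz_width)) g$mz_width else 1),
    adaptive = build_adaptive_grid(rt_span, scan_interval, density_prior(as.data.frame(g$regions))),
    estimate = build_adaptive_grid(
      rt_span, scan_interval,
      estimate_density_prior(samples,
                             n_regions = if (!is.null(g$n_regions)) g$n_regions else 4,
                             fine_width = if (!is.null(g$fine_width)) g$fine_width else 0.5,
                             broad_width = if (!is.null(g$broad_width)) g$broad_width else 2)),
    abort_lcms(sprintf("unknown grid type '%s'", g$type), "lcmsnet_validation_error")
  )
}

pipeline_model_config <- function(cfg) {
  overrides <- cfg$model
  overrides$n_members <- NULL
  overrides$seed <- derive_seed(cfg$seed, 20)
  do.call(member_config, utils::modifyList(
    list(kernel_len = 7, pool_len = 8, spatial_dropout_rate = 0.2,
         l1_coeff = 1e-5, learning_rate = 1e-3, batch_size = 32,
         max_epochs = 30, early_stop_patience = 4, val_fraction = 0.1),
    overrides))
}

pipeline_load_samples <- function(cfg) {
  if (!is.null(cfg$data) && !is.null(cfg$data$mzml_files)) {
    files <- cfg$data$mzml_files
    labels <- cfg$data$labels
    if (is.null(labels) || length(labels) != length(files)) {
      abort_lcms("data$labels must be parallel to data$mzml_files",
                 "lcmsnet_validation_error")
    }
    batches <- cfg$data$batch_ids
    if (is.null(batches)) batches <- rep(NA_character_, length(files))
    mapply(function(f, l, b) read_mzml(f, label = l, batch_id = b),
           files, labels, batches, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else {
    sim_args <- utils::modifyList(cfg$sim, list(seed = derive_seed(cfg$seed, 10)))
    simulate_dataset(do.call(sim_config, sim_args))
  }
}

# Train an ensemble on raw training samples: augment, bin, fit, and select
# the reject threshold on a held-out slice of the training data.
pipeline_fit <- function(cfg, train_samples, grid) {
  labels <- sample_labels(train_samples)
  thr_frac <- if (!is.null(cfg$decision$val_fraction)) cfg$decision$val_fraction else 0.1
  use_auto <- identical(cfg$decision$threshold, "auto") || is.null(cfg$decision$threshold)
  thr_idx <- integer(0)
  if (use_auto) {
    sp <- stratified_split(labels, test_fraction = thr_frac,
                           seed = derive_seed(cfg$seed, 30))
    thr_idx <- which(sp == "test")
  }
  fit_samples <- if (length(thr_idx)) train_samples[-thr_idx] else train_samples
  if (isTRUE(cfg$augment$enabled)) {
    fit_samples <- augment_dataset(fit_samples, augment_config(
      max_shift = if (!is.null(cfg$augment$max_shift)) cfg$augment$max_shift else 10,
      copies_per_sample = if (!is.null(cfg$augment$copies)) cfg$augment$copies else 1,
      seed = derive_seed(cfg$seed, 40)))
  }
  fit_images <- bin_dataset(fit_samples, grid, scale = cfg$scale)
  n_members <- if (!is.null(cfg$model$n_members)) cfg$model$n_members else 5
  model <- train_ensemble(fit_images, n_members = n_members,
                          config = pipeline_model_config(cfg))
  threshold <- 0
  if (use_auto && length(thr_idx)) {
    val_images <- bin_dataset(train_samples[thr_idx], grid, scale = cfg$scale)
    val_probs <- predict_proba(model, val_images)
    threshold <- as.numeric(select_threshold(
      val_probs, labels[thr_idx],
      candidates = if (!is.null(cfg$decision$candidates)) cfg$decision$candidates
        else seq(0, 0.95, by = 0.05),
      class_order = model$class_order))
  } else if (!use_auto) {
    threshold <- cfg$decision$threshold
  }
  list(model = model, threshold = threshold)
}

pipeline_evaluate <- function(model, threshold, test_images, truth) {
  probs <- predict_proba(model, test_images)
  pred <- classify_with_reject(probs, threshold = threshold,
                               class_order = model$class_order)
  accepted <- pred$predicted != REJECTED
  metrics <- if (any(accepted)) {
    macro_metrics(truth[accepted], pred$predicted[accepted],
                  classes = model$class_order)
  } else NULL
  list(predictions = cbind(pred, truth = truth),
       metrics = metrics, rejection_rate = mean(!accepted))
}

metrics_table <- function(ev) {
  m <- ev$metrics
  if (is.null(m)) {
    return(data.frame(scope = "overall", accuracy = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      f1 = NA_real_, rejection_rate = ev$rejection_rate))
  }
  macro_row <- data.frame(scope = "macro", accuracy = m$macro$accuracy,
                          sensitivity = m$macro$sensitivity,
                          specificity = m$macro$specificity, f1 = m$macro$f1,
                          rejection_rate = ev$rejection_rate)
  overall_row <- data.frame(scope = "overall", accuracy = m$overall_accuracy,
                            sensitivity = NA_real_, specificity = NA_real_,
                            f1 = NA_real_, rejection_rate = ev$rejection_rate)
  per <- m$per_class
  per_rows <- data.frame(scope = paste0("class:", per$class),
                         accuracy = per$accuracy, sensitivity = per$sensitivity,
                         specificity = per$specificity, f1 = per$f1,
                         rejection_rate = NA_real_)
  rbind(overall_row, macro_row, per_rows)
}

#' Run the full pipeline end to end
#'
#' Simulates (or loads) labeled LC-HRMS runs, builds the bin grid,
#' splits stratified 75/25, augments and bins the training portion,
#' trains the ensemble, selects the reject threshold on held-out training
#' data, predicts the test set and reports metrics. When `output_dir` is
#' given, the model archive, prediction table, metrics table and a
#' machine-readable run manifest are written there.
#'
#' @param config a [run_config()].
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return List with `model`, `threshold`, `predictions`, `metrics`
#'   (data.frame), `grid`, and `paths` of written artifacts (if any).
#' @export
run_end_to_end <- function(config, output_dir = NULL) {
  validate_run_config(config)
  samples <- pipeline_load_samples(config)
  labels <- sample_labels(samples)
  grid <- pipeline_grid(config, samples)
  sp <- stratified_split(labels, test_fraction =
                           if (!is.null(config$split$test_fraction))
                             config$split$test_fraction else 0.25,
                         seed = derive_seed(config$seed, 50))
  train_samples <- samples[sp == "train"]
  test_samples <- samples[sp == "test"]
  fit <- pipeline_fit(config, train_samples, grid)
  test_images <- bin_dataset(test_samples, grid, scale = config$scale)
  ev <- pipeline_evaluate(fit$model, fit$threshold, test_images,
                          sample_labels(test_samples))
  mt <- metrics_table(ev)
  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(model = file.path(output_dir, "model.rds"),
                  predictions = file.path(output_dir, "predictions.tsv"),
                  metrics = file.path(output_dir, "metrics.tsv"),
                  manifest = file.path(output_dir, "manifest.json"),
                  training_log = file.path(output_dir, "training_log.tsv"))
    log_df <- do.call(rbind, lapply(seq_along(fit$model$members), function(k) {
      cbind(member = k, fit$model$members[[k]]$history)
    }))
    utils::write.table(log_df, paths$training_log, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    save_model(fit$model, paths$model, grid = grid)
    utils::write.table(ev$predictions, paths$predictions, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(mt, paths$metrics, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest <- list(config = unclass(config), threshold = fit$threshold,
                     n_train = length(train_samples), n_test = length(test_samples),
                     class_order = fit$model$class_order,
                     r_version = as.character(getRversion()),
                     package_version = as.character(utils::packageVersion("lcmsnet")))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  list(model = fit$model, threshold = fit$threshold,
       predictions = ev$predictions, metrics = mt, grid = grid, paths = paths)
}

#' Cross-batch robustness protocol
#'
#' Simulates two acquisition batches, trains on the training portion of
#' one batch and evaluates both within-batch (its own held-out test
#' portion) and cross-batch (the entire other batch), in both directions.
#' Reproduces the train-on-one-instrument / test-on-the-other protocol on
#' simulated batches.
#'
#' @param config a [run_config()] (its `sim` settings define classes,
#'   sample counts and noise).
#' @param batch_a,batch_b [batch_profile()]s for the two batches.
#' @return data.frame with one row per condition (`A->A`, `B->B`, `A->B`,
#'   `B->A`): overall accuracy, macro sensitivity / specificity / F1.
#' @export
run_cross_batch <- function(config, batch_a, batch_b) {
  validate_run_config(config)
  sim_args <- utils::modifyList(config$sim, list(seed = derive_seed(config$seed, 10)))
  scfg <- do.call(sim_config, sim_args)
  samples <- simulate_dataset(scfg, batches = list(batch_a, batch_b))
  batches <- sample_batches(samples)
  grid <- pipeline_grid(config, samples)
  one_direction <- function(train_batch, test_batch, tag) {
    tr_all <- samples[batches == train_batch]
    te_other <- samples[batches == test_batch]
    sp <- stratified_split(sample_labels(tr_all),
                           test_fraction = if (!is.null(config$split$test_fraction))
                             config$split$test_fraction else 0.25,
                           seed = derive_seed(config$seed, 50))
    fit <- pipeline_fit(config, tr_all[sp == "train"], grid)
    eval_on <- function(tsamples) {
      imgs <- bin_dataset(tsamples, grid, scale = config$scale)
      ev <- pipeline_evaluate(fit$model, fit$threshold, imgs,
                              sample_labels(tsamples))
      m <- ev$metrics
      data.frame(accuracy = m$overall_accuracy,
                 sensitivity = m$macro$sensitivity,
                 specificity = m$macro$specificity, f1 = m$macro$f1,
                 rejection_rate = ev$rejection_rate)
    }
    within <- eval_on(tr_all[sp == "test"])
    cross <- eval_on(te_other)
    rbind(cbind(condition = sprintf("%s->%s", tag[1], tag[1]), within),
          cbind(condition = sprintf("%s->%s", tag[1], tag[2]), cross))
  }
  out <- rbind(one_direction(batch_a$batch_id, batch_b$batch_id, c("A", "B")),
               one_direction(batch_b$batch_id, batch_a$batch_id, c("B", "A")))
  out[match(c("A->A", "B->B", "A->B", "B->A"), out$condition), , drop = FALSE]
}
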