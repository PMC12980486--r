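#' Simulation configuration for synthetic LC-HRMS runs
#'
#' Defines the study conditions emulated by the generator: a Q-TOF-style
#' centroided acquisition with a regular scan grid over a 12-minute
#' gradient, class-specific marker compounds with Gaussian chromatographic
#' elution profiles, per-sample retention-time drift, lognormal peak-height
#' variation and a sparse background of noise centroids.
#'
#' @param n_classes number of classes (>= 2).
#' @param samples_per_class samples simulated per class; a scalar or a
#'   vector of length `n_classes` (allows imbalance).
#' @param n_markers class-specific marker compounds per class.
#' @param n_shared marker compounds shared by all classes.
#' @param scan_interval time between consecutive scans, seconds.
#' @param acquisition_span total acquisition time, seconds.
#' @param mz_span numeric length-2, the instrument m/z range (Thomson).
#' @param rt_drift_sd standard deviation of the per-sample retention-time
#'   drift, seconds; the drift is applied uniformly to every peak of a run.
#' @param height_cv coefficient of variation of the lognormal peak-height
#'   noise (per peak and run).
#' @param height_range range the per-compound mean apex heights are drawn
#'   from (arbitrary counts).
#' @param rt_sigma_range range of chromatographic peak widths (Gaussian
#'   sigma), seconds.
#' @param n_background number of uniform background noise centroids per run.
#' @param noise_floor mean intensity of background centroids (exponential).
#' @param detection_frac detection threshold as a fraction of a compound's
#'   mean apex height; weaker elution tails are not centroided.
#' @param seed integer seed fixing the full generated output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_classes = 5, samples_per_class = 100, n_markers = 10,
                       n_shared = 10, scan_interval = 3, acquisition_span = 720,
                       mz_span = c(100, 400), rt_drift_sd = 2, height_cv = 0.3,
                       height_range = c(5e3, 5e4), rt_sigma_range = c(2, 5),
                       n_background = 300, noise_floor = 50,
                       detection_frac = 0.01, seed = 1) {
  check_number(n_classes, "n_classes", lower = 2)
  check_number(scan_interval, "scan_interval", lower = 0, strict_lower = TRUE)
  check_number(acquisition_span, "acquisition_span", lower = 0, strict_lower = TRUE)
  check_number(rt_drift_sd, "rt_drift_sd", lower = 0)
  check_number(height_cv, "height_cv", lower = 0)
  check_number(detection_frac, "detection_frac", lower = 0)
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  structure(list(
    n_classes = as.integer(n_classes), samples_per_class = samples_per_class,
    n_markers = as.integer(n_markers), n_shared = as.integer(n_shared),
    scan_interval = scan_interval, acquisition_span = acquisition_span,
    mz_span = as.numeric(mz_span), rt_drift_sd = rt_drift_sd,
    height_cv = height_cv, height_range = as.numeric(height_range),
    rt_sigma_range = as.numeric(rt_sigma_range),
    n_background = as.integer(n_background), noise_floor = noise_floor,
    detection_frac = detection_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Acquisition batch / instrument profile
#'
#' Systematic technical offsets shared by every run of a batch: a
#' retention-time shift, a multiplicative intensity response factor and a
#' mass-axis offset. Emulates the kind of variation seen between
#' instruments or collection periods.
#'
#' @param batch_id batch identifier.
#' @param rt_offset systematic retention-time shift, seconds.
#' @param intensity_scale multiplicative intensity factor (> 0).
#' @param mz_offset systematic m/z shift, Thomson.
#' @param noise_floor mean background intensity for this batch; `NULL`
#'   falls back to the simulation config value.
#' @return A list of class `batch_profile`.
#' @export
batch_profile <- function(batch_id, rt_offset = 0, intensity_scale = 1,
                          mz_offset = 0, noise_floor = NULL) {
  check_number(intensity_scale, "intensity_scale", lower = 0, strict_lower = TRUE)
  structure(list(batch_id = as.character(batch_id), rt_offset = rt_offset,
                 intensity_scale = intensity_scale, mz_offset = mz_offset,
                 noise_floor = noise_floor),
            class = "batch_profile")
}

# Draw marker (rt, mz) positions rejecting near-collisions with `taken`.
draw_markers <- function(n, config, taken) {
  span <- config$acquisition_span
  rt_lo <- 0.05 * span; rt_hi <- 0.95 * span
  mz_lo <- config$mz_span[1] + 2; mz_hi <- config$mz_span[2] - 2
  out <- matrix(NA_real_, n, 2)
  k <- 0
  guard <- 0
  while (k < n) {
    guard <- guard + 1
    if (guard > 10000 * n) {
      abort_lcms("could not place disjoint markers; span too crowded",
                 "lcmsnet_parameter_error")
    }
    rt <- stats::runif(1, rt_lo, rt_hi)
    mz <- stats::runif(1, mz_lo, mz_hi)
    if (nrow(taken)) {
      clash <- abs(taken[, 1] - rt) < 15 & abs(taken[, 2] - mz) < 3
      if (any(clash)) next
    }
    k <- k + 1
    out[k, ] <- c(rt, mz)
    taken <- rbind(taken, c(rt, mz))
  }
  list(markers = out, taken = taken)
}

#' Generate class signatures (marker compound panels)
#'
#' Each class receives `n_markers` marker compounds at positions drawn
#' uniformly over the retention-time / m/z span; marker sets of distinct
#' classes are disjoint in (rt, mz). A shared panel of compounds common to
#' all classes is attached as the `"shared_peaks"` attribute.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_markers markers per class (>= 1).
#' @param config a [sim_config()]; its seed makes the draw deterministic.
#' @return A list of `class_signature` objects (fields `class_id`,
#'   `markers`), one per class, with attribute `shared_peaks`.
#' @export
make_signatures <- function(n_classes = config$n_classes,
                            n_markers = config$n_markers,
                            config = sim_config()) {
  if (n_classes < 2) abort_lcms("n_classes must be >= 2", "lcmsnet_parameter_error")
  if (n_markers < 1) abort_lcms("n_markers must be >= 1", "lcmsnet_parameter_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 101))
  taken <- matrix(numeric(0), 0, 2)
  marker_df <- function(pos) {
    data.frame(
      rt_center = pos[, 1], mz_center = pos[, 2],
      mean_height = stats::runif(nrow(pos), config$height_range[1], config$height_range[2]),
      rt_sigma = stats::runif(nrow(pos), config$rt_sigma_range[1], config$rt_sigma_range[2])
    )
  }
  sigs <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    d <- draw_markers(n_markers, config, taken)
    taken <- d$taken
    sigs[[k]] <- structure(
      list(class_id = sprintf("class%02d", k), markers = marker_df(d$markers)),
      class = "class_signature"
    )
  }
  shared <- if (config$n_shared > 0) {
    d <- draw_markers(config$n_shared, config, taken)
    marker_df(d$markers)
  } else {
    marker_df(matrix(numeric(0), 0, 2))
  }
  attr(sigs, "shared_peaks") <- shared
  sigs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate one LC-HRMS run
#'
#' Every marker of the class signature (plus the shared panel) elutes as a
#' Gaussian chromatographic peak centered at
#' `rt_center + sample drift + batch rt_offset` with width `rt_sigma`,
#' sampled at the regular scan times. Each scan contributes one centroid at
#' `mz_center + batch mz_offset` with intensity
#' `height x Gaussian factor x lognormal noise x intensity_scale`; points
#' whose pre-scale intensity falls below the detection threshold
#' (`detection_frac x mean_height`) are not emitted, so the retained point
#' set is independent of the batch intensity response. Uniform background
#' centroids with exponential intensities are added on top.
#'
#' @param signature a `class_signature` from [make_signatures()].
#' @param batch a [batch_profile()].
#' @param config a [sim_config()].
#' @param sample_seed integer seed for this run's random draws.
#' @param shared_peaks data.frame of shared compounds (as produced by
#'   [make_signatures()]), or `NULL`.
#' @param sample_id identifier for the run.
#' @return An [lcms_sample()] labeled with the signature's class and the
#'   batch id.
#' @export
simulate_sample <- function(signature, batch, config, sample_seed,
                            shared_peaks = NULL, sample_id = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(sample_seed) %% 2147483629)
  peaks <- signature$markers
  if (!is.null(shared_peaks) && nrow(shared_peaks)) {
    peaks <- rbind(peaks, shared_peaks)
  }
  drift <- stats::rnorm(1, 0, config$rt_drift_sd)
  scan_times <- seq(0, config$acquisition_span, by = config$scan_interval)
  sdlog <- sqrt(log(1 + config$height_cv^2))
  noise_floor <- if (!is.null(batch$noise_floor)) batch$noise_floor else config$noise_floor

  pts <- vector("list", nrow(peaks) + 1L)
  for (i in seq_len(nrow(peaks))) {
    center <- peaks$rt_center[i] + drift + batch$rt_offset
    amp <- peaks$mean_height[i] *
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    gauss <- exp(-(scan_times - center)^2 / (2 * peaks$rt_sigma[i]^2))
    intens <- amp * gauss
    keep <- intens >= config$detection_frac * peaks$mean_height[i]
    if (!any(keep)) next
    pts[[i]] <- data.frame(
      rt = scan_times[keep],
      mz = rep(peaks$mz_center[i] + batch$mz_offset, sum(keep)),
      intensity = intens[keep] * batch$intensity_scale
    )
  }
  if (config$n_background > 0) {
    nb <- config$n_background
    pts[[length(pts)]] <- data.frame(
      rt = sample(scan_times, nb, replace = TRUE),
      mz = stats::runif(nb, config$mz_span[1], config$mz_span[2]),
      intensity = stats::rexp(nb, rate = 1 / noise_floor) * batch$intensity_scale
    )
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%s_s%d", signature$class_id, batch$batch_id,
                         as.integer(sample_seed))
  }
  lcms_sample(points, sample_id = sample_id, label = signature$class_id,
              batch_id = batch$batch_id,
              acquisition_span = c(0, config$acquisition_span))
}

#' Simulate a labeled collection of LC-HRMS runs
#'
#' Generates `samples_per_class[k]` runs of class `k` for every requested
#' batch, with per-run seeds derived from `config$seed` so the whole
#' dataset is a pure function of the configuration.
#'
#' @param config a [sim_config()].
#' @param signatures class signatures; defaults to [make_signatures()] under
#'   the config seed.
#' @param batches list of [batch_profile()]s; defaults to a single neutral
#'   batch.
#' @return A list of [lcms_sample()]s with attribute `signatures`.
#' @export
simulate_dataset <- function(config = sim_config(), signatures = NULL,
                             batches = NULL) {
  if (is.null(signatures)) signatures <- make_signatures(config = config)
  if (is.null(batches)) batches <- list(batch_profile("batch1"))
  if (!length(batches)) {
    abort_lcms("at least one batch profile is required", "lcmsnet_parameter_error")
  }
  shared <- attr(signatures, "shared_peaks")
  out <- list()
  counter <- 0
  for (b in seq_along(batches)) {
    for (k in seq_along(signatures)) {
      for (j in seq_len(config$samples_per_class[k])) {
        counter <- counter + 1
        sid <- sprintf("%s_%s_%03d", signatures[[k]]$class_id,
                       batches[[b]]$batch_id, j)
        out[[counter]] <- simulate_sample(
          signatures[[k]], batches[[b]], config,
          sample_seed = derive_seed(config$seed, c(200, b, k, j)),
          shared_peaks = shared, sample_id = sid
        )
      }
    }
  }
  attr(out, "signatures") <- signatures
  out
}
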