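#' Augmentation configuration
#'
#' @param max_shift maximum absolute retention-time shift, seconds
#'   (default 10, matching typical between-run drift magnitudes).
#' @param copies_per_sample shifted copies generated per input sample.
#' @param seed integer seed fixing the drawn shifts.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(max_shift = 10, copies_per_sample = 1, seed = 1) {
  check_number(max_shift, "max_shift", lower = 0)
  check_number(copies_per_sample, "copies_per_sample", lower = 0)
  structure(list(max_shift = max_shift,
                 copies_per_sample = as.integer(copies_per_sample),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Shift a sample along the retention-time axis
#'
#' Adds `delta` seconds to every point's retention time; points pushed
#' outside the acquisition span are dropped. Label, batch and span are
#' preserved and the (rt, mz) sort order is restored.
#'
#' @param sample an [lcms_sample()].
#' @param delta shift in seconds (may be negative).
#' @return The shifted [lcms_sample()].
#' @export
shift_rt <- function(sample, delta) {
  p <- sample$points
  p$rt <- p$rt + delta
  span <- sample$acquisition_span
  p <- p[p$rt >= span[1] & p$rt <= span[2], , drop = FALSE]
  lcms_sample(p, sample_id = sample$sample_id, label = sample$label,
              batch_id = sample$batch_id, acquisition_span = span)
}

#' Expand a dataset with random retention-time shifts
#'
#' For every input sample the original is kept and `copies_per_sample`
#' shifted copies are added, with shifts drawn from
#' `Uniform(-max_shift, +max_shift)` deterministically under the config
#' seed. Copies inherit label and batch.
#'
#' @param samples list of [lcms_sample()]s.
#' @param config an [augment_config()].
#' @return List of samples: originals followed by their shifted copies.
#' @export
augment_dataset <- function(samples, config = augment_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 301))
  out <- as.list(samples)
  n0 <- length(out)
  k <- n0
  for (i in seq_len(n0)) {
    for (j in seq_len(config$copies_per_sample)) {
      delta <- stats::runif(1, -config$max_shift, config$max_shift)
      cp <- shift_rt(out[[i]], delta)
      cp$sample_id <- sprintf("%s_aug%d", cp$sample_id, j)
      attr(cp, "rt_shift") <- delta
      k <- k + 1
      out[[k]] <- cp
    }
  }
  out
}

#' Balance classes by random oversampling
#'
#' Brings every class up to the majority-class count by drawing duplicates
#' uniformly with replacement from that class. All original items are
#' retained; the draw is deterministic under `seed`.
#'
#' @param items list of labeled items (anything with a `label` field, e.g.
#'   samples or pseudoimages), or an arbitrary list if `labels` is given.
#' @param labels optional character vector of labels parallel to `items`.
#' @param seed integer seed.
#' @return The balanced list of items; the selected indices into the input
#'   are attached as attribute `"index"`.
#' @export
oversample <- function(items, labels = NULL, seed = 1) {
  if (is.null(labels)) {
    labels <- vapply(items, function(x) as.character(x$label), character(1))
  }
  if (length(labels) != length(items)) {
    abort_lcms("`labels` must be parallel to `items`", "lcmsnet_parameter_error")
  }
  if (any(is.na(labels))) {
    abort_lcms("all items must be labeled for oversampling", "lcmsnet_parameter_error")
  }
  tab <- table(labels)
  if (!length(tab) || any(tab == 0)) {
    abort_lcms("every class needs at least one item", "lcmsnet_parameter_error")
  }
  target <- max(tab)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 302))
  sel <- seq_along(items)
  for (cl in names(tab)) {
    deficit <- target - tab[[cl]]
    if (deficit > 0) {
      pool <- which(labels == cl)
      sel <- c(sel, sample(pool, deficit, replace = TRUE))
    }
  }
  out <- items[sel]
  attr(out, "index") <- sel
  out
}
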