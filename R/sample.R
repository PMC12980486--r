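#' Construct an LC-HRMS sample
#'
#' A sample is one LC-HRMS run represented as a point cloud: each point is a
#' centroided peak with a retention time (seconds), an m/z value (Thomson)
#' and a non-negative intensity. Points are kept sorted lexicographically by
#' (rt, mz), which downstream operations rely on.
#'
#' @param points data.frame with numeric columns `rt`, `mz`, `intensity`.
#' @param sample_id character scalar identifying the run.
#' @param label class label of the run, or `NA` if unknown.
#' @param batch_id acquisition batch / instrument identifier, or `NA`.
#' @param acquisition_span numeric length-2 vector `(rt_min, rt_max)` in
#'   seconds; defaults to the range of the point retention times.
#' @return An object of class `lcms_sample`: a list with fields `sample_id`,
#'   `points`, `label`, `batch_id`, `acquisition_span`.
#' @examples
#' s <- lcms_sample(data.frame(rt = c(2, 1), mz = c(150, 200), intensity = c(5, 3)),
#'                  sample_id = "run1")
#' s$points$rt  # sorted
#' @export
lcms_sample <- function(points, sample_id, label = NA_character_,
                        batch_id = NA_character_, acquisition_span = NULL) {
  if (!is.data.frame(points) || !all(c("rt", "mz", "intensity") %in% names(points))) {
    abort_lcms("`points` must be a data.frame with columns rt, mz, intensity",
               "lcmsnet_parameter_error")
  }
  points <- points[, c("rt", "mz", "intensity")]
  if (nrow(points)) {
    if (any(points$rt < 0) || any(points$mz <= 0) || any(points$intensity < 0)) {
      abort_lcms("point invariants violated: rt >= 0, mz > 0, intensity >= 0",
                 "lcmsnet_parameter_error")
    }
    points <- points[order(points$rt, points$mz), , drop = FALSE]
    rownames(points) <- NULL
  }
  if (is.null(acquisition_span)) {
    acquisition_span <- if (nrow(points)) range(points$rt) else c(0, 0)
  }
  acquisition_span <- as.numeric(acquisition_span)
  if (length(acquisition_span) != 2L || acquisition_span[2] < acquisition_span[1]) {
    abort_lcms("`acquisition_span` must be (rt_min, rt_max) with rt_max >= rt_min",
               "lcmsnet_parameter_error")
  }
  if (nrow(points) && (min(points$rt) < acquisition_span[1] ||
                       max(points$rt) > acquisition_span[2])) {
    abort_lcms("all point rt values must lie within acquisition_span",
               "lcmsnet_parameter_error")
  }
  structure(
    list(sample_id = as.character(sample_id), points = points,
         label = label, batch_id = batch_id,
         acquisition_span = acquisition_span),
    class = "lcms_sample"
  )
}

#' @export
print.lcms_sample <- function(x, ...) {
  cat(sprintf("<lcms_sample> %s: %d points, rt span [%.1f, %.1f] s, label=%s, batch=%s\n",
              x$sample_id, nrow(x$points),
              x$acquisition_span[1], x$acquisition_span[2],
              as.character(x$label), as.character(x$batch_id)))
  invisible(x)
}

#' Validate an `lcms_sample` object
#'
#' Checks the class invariants: point columns, non-negativity, (rt, mz)
#' sort order and containment of retention times in the acquisition span.
#'
#' @param x object to validate.
#' @return `x`, invisibly; errors if an invariant is violated.
#' @export
validate_sample <- function(x) {
  if (!inherits(x, "lcms_sample")) {
    abort_lcms("not an lcms_sample", "lcmsnet_parameter_error")
  }
  p <- x$points
  if (nrow(p)) {
    o <- order(p$rt, p$mz)
    if (!identical(o, seq_len(nrow(p)))) {
      abort_lcms("points are not sorted by (rt, mz)", "lcmsnet_invariant_error")
    }
    if (min(p$rt) < x$acquisition_span[1] || max(p$rt) > x$acquisition_span[2]) {
      abort_lcms("point rt outside acquisition_span", "lcmsnet_invariant_error")
    }
    if (any(p$intensity < 0) || any(p$mz <= 0)) {
      abort_lcms("negative intensity or non-positive mz", "lcmsnet_invariant_error")
    }
  }
  invisible(x)
}

#' Extract labels or batch ids from a sample collection
#'
#' @param samples list of [lcms_sample()]s.
#' @return Character vector parallel to `samples`.
#' @export
sample_labels <- function(samples) {
  vapply(samples, function(s) as.character(s$label), character(1))
}

#' @rdname sample_labels
#' @export
sample_batches <- function(samples) {
  vapply(samples, function(s) as.character(s$batch_id), character(1))
}
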