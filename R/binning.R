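# Shared edge builder: equally spaced edges of width `width` over `span`,
# with a final narrower bin so the last edge lands exactly on span[2].
edges_over_span <- function(span, width, name) {
  check_number(width, name, lower = 0, strict_lower = TRUE)
  if (!(span[2] > span[1])) {
    abort_lcms("span must be non-degenerate", "lcmsnet_parameter_error")
  }
  e <- seq(span[1], span[2], by = width)
  if (utils::tail(e, 1) < span[2]) e <- c(e, span[2])
  e
}

#' Build a uniform RT x m/z bin grid
#'
#' Bins are half-open `[edge_i, edge_{i+1})`; the final bin of each axis is
#' closed so the upper span bound is included. The last bin may be narrower
#' than `width` so the grid ends exactly at the span's upper bound.
#'
#' @param rt_span,mz_span numeric length-2 spans (seconds / Thomson).
#' @param rt_width,mz_width bin widths (> 0).
#' @return An object of class `bin_grid` with fields `rt_edges`, `mz_edges`.
#' @examples
#' g <- build_uniform_grid(c(0, 10), 2, c(100, 105), 2)
#' g$mz_edges  # 100 102 104 105 -- final bin narrower
#' @export
build_uniform_grid <- function(rt_span, rt_width, mz_span, mz_width) {
  new_bin_grid(edges_over_span(rt_span, rt_width, "rt_width"),
               edges_over_span(mz_span, mz_width, "mz_width"))
}

new_bin_grid <- function(rt_edges, mz_edges) {
  if (length(rt_edges) < 2 || length(mz_edges) < 2 ||
      any(diff(rt_edges) <= 0) || any(diff(mz_edges) <= 0)) {
    abort_lcms("bin edges must be strictly increasing with >= 1 bin per axis",
               "lcmsnet_parameter_error")
  }
  structure(list(rt_edges = rt_edges, mz_edges = mz_edges), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d RT bins [%.1f, %.1f] s x %d m/z bins [%.1f, %.1f] Th\n",
              length(x$rt_edges) - 1, min(x$rt_edges), max(x$rt_edges),
              length(x$mz_edges) - 1, min(x$mz_edges), max(x$mz_edges)))
  invisible(x)
}

#' m/z density prior for adaptive binning
#'
#' A contiguous partition of the m/z span into regions, each with its own
#' bin width: regions expected to hold many metabolites get fine bins,
#' sparse regions get broad bins.
#'
#' @param regions data.frame with columns `mz_lo`, `mz_hi`, `bin_width`;
#'   regions must be sorted and abutting (`mz_hi[k] == mz_lo[k+1]`).
#' @return An object of class `density_prior`.
#' @export
density_prior <- function(regions) {
  req <- c("mz_lo", "mz_hi", "bin_width")
  if (!is.data.frame(regions) || !all(req %in% names(regions))) {
    abort_lcms("`regions` must have columns mz_lo, mz_hi, bin_width",
               "lcmsnet_parameter_error")
  }
  regions <- regions[, req]
  if (any(regions$bin_width <= 0) || any(regions$mz_hi <= regions$mz_lo)) {
    abort_lcms("regions must have positive width and bin_width",
               "lcmsnet_parameter_error")
  }
  n <- nrow(regions)
  if (n > 1 && any(abs(regions$mz_hi[-n] - regions$mz_lo[-1]) > 1e-9)) {
    abort_lcms("prior regions must abut: region k's mz_hi must equal region k+1's mz_lo",
               "lcmsnet_validation_error")
  }
  structure(list(regions = regions), class = "density_prior")
}

#' Build an adaptive bin grid
#'
#' RT bins are uniform with width equal to the instrument's scan
#' (acquisition) interval, so each bin matches the acquisition frequency;
#' m/z bins follow a [density_prior()], region by region, finer where more
#' metabolites are expected.
#'
#' @param rt_span numeric length-2 RT span, seconds.
#' @param acquisition_interval scan interval, seconds (> 0).
#' @param prior a [density_prior()] covering the m/z span.
#' @return A `bin_grid`.
#' @export
build_adaptive_grid <- function(rt_span, acquisition_interval, prior) {
  if (!inherits(prior, "density_prior")) prior <- density_prior(prior)
  rt_edges <- edges_over_span(rt_span, acquisition_interval, "acquisition_interval")
  reg <- prior$regions
  mz_edges <- reg$mz_lo[1]
  for (k in seq_len(nrow(reg))) {
    e <- edges_over_span(c(reg$mz_lo[k], reg$mz_hi[k]), reg$bin_width[k], "bin_width")
    mz_edges <- c(mz_edges, e[-1])
  }
  new_bin_grid(rt_edges, mz_edges)
}

#' Estimate an m/z density prior from data
#'
#' Pools the points of all samples, splits the m/z span at empirical
#' quantiles of the pooled m/z values (so regions hold equal point counts),
#' and assigns `fine_width` to regions whose point density exceeds the
#' median density along the m/z axis (width-weighted over regions),
#' `broad_width` otherwise. Deterministic given the input.
#'
#' @param samples list of [lcms_sample()]s (>= 1 point overall).
#' @param n_regions number of regions to form.
#' @param fine_width,broad_width bin widths (Th) for dense / sparse regions.
#' @return A [density_prior()].
#' @export
estimate_density_prior <- function(samples, n_regions = 4, fine_width = 0.5,
                                   broad_width = 2) {
  if (inherits(samples, "lcms_sample")) samples <- list(samples)
  mz <- unlist(lapply(samples, function(s) s$points$mz), use.names = FALSE)
  if (!length(mz)) abort_lcms("no points to estimate a prior from", "lcmsnet_parameter_error")
  probs <- seq(0, 1, length.out = n_regions + 1)
  cuts <- unname(stats::quantile(mz, probs = probs, type = 7))
  cuts[1] <- min(mz); cuts[n_regions + 1] <- max(mz)
  cuts <- unique(cuts)
  if (length(cuts) < 2) {
    abort_lcms("degenerate m/z distribution; cannot form regions", "lcmsnet_parameter_error")
  }
  nreg <- length(cuts) - 1
  counts <- vapply(seq_len(nreg), function(k) {
    if (k < nreg) sum(mz >= cuts[k] & mz < cuts[k + 1]) else sum(mz >= cuts[k])
  }, numeric(1))
  widths <- diff(cuts)
  dens <- counts / widths
  # median density along the m/z axis (width-weighted): with quantile-built
  # regions a plain median over regions would always split them half/half
  o <- order(dens)
  cum <- cumsum(widths[o])
  med_dens <- dens[o][which(cum >= sum(widths) / 2)[1]]
  width <- ifelse(dens > med_dens, fine_width, broad_width)
  density_prior(data.frame(mz_lo = cuts[-length(cuts)], mz_hi = cuts[-1],
                           bin_width = width))
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  i
}

#' Bin a sample's point cloud into a pseudoimage
#'
#' Each point is mapped to the grid cell containing its (rt, mz); the cell
#' value is the maximum intensity among its points, empty cells are zero.
#' Points outside the grid span are silently dropped and counted in the
#' `n_dropped` field of the result.
#'
#' @param sample an [lcms_sample()].
#' @param grid a `bin_grid`.
#' @return An object of class `pseudoimage`: `values` is an
#'   `n_rt x n_mz` matrix (RT rows, m/z columns), plus `grid`, `n_dropped`,
#'   and the sample's `sample_id`, `label`, `batch_id`.
#' @export
bin_sample <- function(sample, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  n_rt <- length(grid$rt_edges) - 1L
  n_mz <- length(grid$mz_edges) - 1L
  values <- matrix(0, n_rt, n_mz)
  p <- sample$points
  dropped <- 0L
  if (nrow(p)) {
    ri <- bin_index(p$rt, grid$rt_edges)
    mi <- bin_index(p$mz, grid$mz_edges)
    keep <- !is.na(ri) & !is.na(mi)
    dropped <- sum(!keep)
    if (any(keep)) {
      idx <- (mi[keep] - 1L) * n_rt + ri[keep]
      v <- p$intensity[keep]
      o <- order(idx, v)                 # last occurrence per cell = max
      idx <- idx[o]; v <- v[o]
      last <- !duplicated(idx, fromLast = TRUE)
      values[idx[last]] <- v[last]
    }
  }
  structure(list(values = values, grid = grid, n_dropped = dropped,
                 sample_id = sample$sample_id, label = sample$label,
                 batch_id = sample$batch_id),
            class = "pseudoimage")
}

#' @export
print.pseudoimage <- function(x, ...) {
  cat(sprintf("<pseudoimage> %s: %d RT bins x %d m/z bins, %d points dropped, label=%s\n",
              x$sample_id, nrow(x$values), ncol(x$values), x$n_dropped,
              as.character(x$label)))
  invisible(x)
}

#' Min-max scale a pseudoimage
#'
#' With `mode = "column"` (default) every m/z column is scaled
#' independently over the RT dimension:
#' `out[, m] = (in[, m] - min) / (max - min)`; constant columns map to
#' zero. This equalizes the dynamic range of each m/z channel, which the
#' per-channel depthwise convolutions downstream assume. `mode = "global"`
#' scales the whole matrix by its global min/max instead.
#'
#' @param image a `pseudoimage` with non-negative values.
#' @param mode `"column"` or `"global"`.
#' @return The scaled `pseudoimage`, values in `[0, 1]`; idempotent.
#' @export
scale_minmax <- function(image, mode = c("column", "global")) {
  mode <- match.arg(mode)
  v <- image$values
  if (mode == "column") {
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1                   # constant columns -> all zero
    v <- sweep(sweep(v, 2, lo, "-"), 2, rng, "/")
  } else {
    lo <- min(v); hi <- max(v)
    v <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  }
  image$values <- v
  image
}

#' Bin and scale a collection of samples
#'
#' Convenience wrapper applying [bin_sample()] and [scale_minmax()] to each
#' sample of a collection.
#'
#' @param samples list of [lcms_sample()]s.
#' @param grid a `bin_grid`.
#' @param scale `"column"`, `"global"` or `"none"`.
#' @return List of `pseudoimage`s.
#' @export
bin_dataset <- function(samples, grid, scale = "column") {
  lapply(samples, function(s) {
    img <- bin_sample(s, grid)
    if (scale != "none") img <- scale_minmax(img, mode = scale)
    img
  })
}
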