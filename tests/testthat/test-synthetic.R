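test_that("signatures have the requested counts and are disjoint across classes", {
  cfg <- tiny_sim(n_classes = 5, n_markers = 10)
  sigs <- make_signatures(5, 10, cfg)
  expect_length(sigs, 5)
  expect_true(all(vapply(sigs, function(s) nrow(s$markers), numeric(1)) == 10))
  all_pos <- do.call(rbind, lapply(sigs, function(s)
    s$markers[, c("rt_center", "mz_center")]))
  # no two markers of any classes collide in both rt and mz
  d_rt <- abs(outer(all_pos$rt_center, all_pos$rt_center, "-"))
  d_mz <- abs(outer(all_pos$mz_center, all_pos$mz_center, "-"))
  clash <- d_rt < 15 & d_mz < 3
  diag(clash) <- FALSE
  expect_false(any(clash))
  expect_error(make_signatures(1, 5, cfg), class = "lcmsnet_parameter_error")
})

test_that("signature generation is deterministic in the seed and varies across seeds", {
  a <- make_signatures(config = tiny_sim(seed = 9))
  b <- make_signatures(config = tiny_sim(seed = 9))
  c <- make_signatures(config = tiny_sim(seed = 10))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a[[1]]$markers, c[[1]]$markers)))
})

test_that("elution profiles peak at the scan nearest the shifted center", {
  cfg <- tiny_sim(scan_interval = 1, rt_drift_sd = 0, height_cv = 0,
                  n_background = 0, n_shared = 0)
  sig <- structure(list(class_id = "c1", markers = data.frame(
    rt_center = 150.2, mz_center = 200, mean_height = 1e4, rt_sigma = 3)),
    class = "class_signature")
  s <- simulate_sample(sig, batch_profile("b"), cfg, sample_seed = 1)
  apex <- s$points$rt[which.max(s$points$intensity)]
  expect_equal(apex, 150)  # nearest integer scan to 150.2
  # Gaussian shape: symmetric neighbors around the true center
  i149 <- s$points$intensity[s$points$rt == 149]
  i151 <- s$points$intensity[s$points$rt == 151]
  expect_true(i151 > i149)  # 151 is nearer to 150.2 than 149
})

test_that("batch rt_offset shifts every marker apex by the offset", {
  cfg <- tiny_sim(scan_interval = 1, rt_drift_sd = 0, n_background = 0)
  sigs <- make_signatures(config = cfg)
  s0 <- simulate_sample(sigs[[1]], batch_profile("b0", rt_offset = 0), cfg, 5,
                        shared_peaks = attr(sigs, "shared_peaks"))
  s5 <- simulate_sample(sigs[[1]], batch_profile("b5", rt_offset = 5), cfg, 5,
                        shared_peaks = attr(sigs, "shared_peaks"))
  for (i in seq_len(nrow(sigs[[1]]$markers))) {
    mz <- sigs[[1]]$markers$mz_center[i]
    apex0 <- with(s0$points[s0$points$mz == mz, ], rt[which.max(intensity)])
    apex5 <- with(s5$points[s5$points$mz == mz, ], rt[which.max(intensity)])
    expect_equal(apex5 - apex0, 5)
  }
})

test_that("intensity_scale doubles marker intensities point for point", {
  cfg <- tiny_sim(n_background = 10)
  sigs <- make_signatures(config = cfg)
  s1 <- simulate_sample(sigs[[1]], batch_profile("b", intensity_scale = 1), cfg, 3)
  s2 <- simulate_sample(sigs[[1]], batch_profile("b", intensity_scale = 2), cfg, 3)
  marker_mz <- sigs[[1]]$markers$mz_center
  m1 <- s1$points[s1$points$mz %in% marker_mz, ]
  m2 <- s2$points[s2$points$mz %in% marker_mz, ]
  expect_equal(nrow(m1), nrow(m2))  # detection set is scale-invariant
  expect_equal(m2$intensity, 2 * m1$intensity)
})

test_that("dataset simulation is deterministic and respects per-class counts", {
  cfg <- tiny_sim(samples_per_class = c(4, 2))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_length(d1, 6)
  expect_identical(table(sample_labels(d1)),
                   table(factor(c(rep("class01", 4), rep("class02", 2)))))
  expect_identical(lapply(d1, `[[`, "points"), lapply(d2, `[[`, "points"))
})

test_that("two batches separate by the configured rt offset in mean apex RT", {
  cfg <- tiny_sim(samples_per_class = 4, rt_drift_sd = 1, scan_interval = 2,
                  n_background = 0)
  sigs <- make_signatures(config = cfg)
  ds <- simulate_dataset(cfg, signatures = sigs,
                         batches = list(batch_profile("A"),
                                        batch_profile("B", rt_offset = 6)))
  mz <- sigs[[1]]$markers$mz_center[1]
  apex <- function(s) {
    p <- s$points[s$points$mz == mz, ]
    if (!nrow(p)) return(NA_real_)
    p$rt[which.max(p$intensity)]
  }
  cls1 <- sample_labels(ds) == "class01"
  a <- mean(vapply(ds[cls1 & sample_batches(ds) == "A"], apex, numeric(1)), na.rm = TRUE)
  b <- mean(vapply(ds[cls1 & sample_batches(ds) == "B"], apex, numeric(1)), na.rm = TRUE)
  expect_lt(abs((b - a) - 6), cfg$scan_interval)
})

test_that("markers are recoverable in the binned image", {
  cfg <- tiny_sim(n_background = 20)
  sigs <- make_signatures(config = cfg)
  ds <- simulate_dataset(cfg, signatures = sigs)
  grid <- build_uniform_grid(c(0, cfg$acquisition_span), cfg$scan_interval,
                             cfg$mz_span, 2)
  img <- bin_sample(ds[[1]], grid)
  mk <- sigs[[1]]$markers
  for (i in seq_len(nrow(mk))) {
    r <- findInterval(mk$rt_center[i], grid$rt_edges, rightmost.closed = TRUE)
    m <- findInterval(mk$mz_center[i], grid$mz_edges, rightmost.closed = TRUE)
    # apex may fall in the bin of the drifted center; check a small window
    rwin <- max(1, r - 2):min(nrow(img$values), r + 2)
    expect_gt(max(img$values[rwin, m]), 0)
  }
})

test_that("noise-free, drift-free replicates of a class are identical", {
  cfg <- tiny_sim(height_cv = 0, rt_drift_sd = 0, n_background = 0,
                  samples_per_class = 2)
  ds <- simulate_dataset(cfg)
  grid <- build_uniform_grid(c(0, cfg$acquisition_span), cfg$scan_interval,
                             cfg$mz_span, 2)
  imgs <- bin_dataset(ds, grid, scale = "none")
  labs <- sample_labels(ds)
  pair <- which(labs == "class01")
  expect_equal(imgs[[pair[1]]]$values, imgs[[pair[2]]]$values)
})
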