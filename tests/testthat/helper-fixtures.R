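# Shared fixtures: tiny simulation settings and independent oracles used
# across test files. Everything is generated in code; no stored data.

tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(n_classes = 2, samples_per_class = 3, n_markers = 4, n_shared = 2,
         scan_interval = 5, acquisition_span = 300, mz_span = c(100, 300),
         rt_drift_sd = 1, height_cv = 0.2, n_background = 40, seed = 42),
    list(...)
  )
  do.call(sim_config, args)
}

random_sample <- function(n_points, seed, rt_span = c(0, 100),
                          mz_span = c(100, 500)) {
  set.seed(seed)
  lcms_sample(
    data.frame(rt = runif(n_points, rt_span[1], rt_span[2]),
               mz = runif(n_points, mz_span[1], mz_span[2]),
               intensity = rexp(n_points, 1 / 100)),
    sample_id = sprintf("rand%d", seed),
    acquisition_span = rt_span
  )
}

# Independent brute-force binning oracle: explicit per-bin loop over all
# points, respecting half-open bins with a closed final bin.
brute_force_bin <- function(sample, grid) {
  re <- grid$rt_edges; me <- grid$mz_edges
  n_rt <- length(re) - 1; n_mz <- length(me) - 1
  out <- matrix(0, n_rt, n_mz)
  p <- sample$points
  for (r in seq_len(n_rt)) {
    in_r <- if (r < n_rt) p$rt >= re[r] & p$rt < re[r + 1]
            else p$rt >= re[r] & p$rt <= re[r + 1]
    for (m in seq_len(n_mz)) {
      in_m <- if (m < n_mz) p$mz >= me[m] & p$mz < me[m + 1]
              else p$mz >= me[m] & p$mz <= me[m + 1]
      hit <- in_r & in_m
      if (any(hit)) out[r, m] <- max(p$intensity[hit])
    }
  }
  out
}

# Independent exact Wilcoxon p-value: enumerate all 2^N sign assignments
# of the ranked |d| and count how extreme the observed positive-rank sum is.
enumerate_wilcoxon_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  n <- length(d)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(combos, 1, function(s) sum(r[as.logical(s)]))
  switch(alternative,
         greater = mean(W_all >= W_obs - 1e-9),
         less = mean(W_all <= W_obs + 1e-9),
         two.sided = min(1, 2 * min(mean(W_all >= W_obs - 1e-9),
                                    mean(W_all <= W_obs + 1e-9))))
}

# Hand-coded BH step-up oracle.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Two-class pseudoimage fixture with disjoint active channels per class:
# linearly separable by construction.
separable_images <- function(n_per_class = 12, n_rt = 24, n_mz = 8, seed = 1) {
  set.seed(seed)
  mk <- function(label, chans, id) {
    v <- matrix(abs(rnorm(n_rt * n_mz, 0, 0.02)), n_rt, n_mz)
    for (ch in chans) v[sample(n_rt, 3), ch] <- 1
    structure(list(values = v, grid = NULL, n_dropped = 0L,
                   sample_id = id, label = label, batch_id = NA_character_),
              class = "pseudoimage")
  }
  imgs <- c(
    lapply(seq_len(n_per_class), function(i) mk("A", 1:3, sprintf("A%02d", i))),
    lapply(seq_len(n_per_class), function(i) mk("B", 6:8, sprintf("B%02d", i)))
  )
  imgs
}

tiny_member_config <- function(...) {
  args <- utils::modifyList(
    list(kernel_len = 3, pool_len = 2, spatial_dropout_rate = 0.1,
         l1_coeff = 1e-4, learning_rate = 5e-3, batch_size = 8,
         max_epochs = 15, early_stop_patience = 5, val_fraction = 0.2,
         seed = 7),
    list(...)
  )
  do.call(member_config, args)
}
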