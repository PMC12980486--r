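test_that("member construction validates architecture bounds", {
  expect_error(build_member(tiny_member_config(), c(10, 4), 1),
               class = "lcmsnet_parameter_error")
  expect_error(build_member(tiny_member_config(kernel_len = 20), c(10, 4), 2),
               class = "lcmsnet_parameter_error")
  expect_error(member_config(spatial_dropout_rate = 1),
               class = "lcmsnet_parameter_error")
  m <- build_member(tiny_member_config(), c(10, 4), 3)
  expect_identical(m$input_shape, c(10L, 4L))
})

test_that("identity kernels with unit pooling reproduce the normalized input", {
  cfg <- tiny_member_config(kernel_len = 1, pool_len = 1,
                            spatial_dropout_rate = 0)
  m <- build_member(cfg, c(8, 3), 2)
  m$params$conv_w[] <- 1   # single identity tap per channel
  m$params$conv_b[] <- 0
  set.seed(5)
  x <- array(runif(2 * 8 * 3), dim = c(2, 8, 3))
  f <- member_features(m, x)
  expect_equal(f$conv, f$bn)
  expect_equal(f$pool, f$bn)
})

test_that("depthwise convolution mixes no channels", {
  cfg <- tiny_member_config(kernel_len = 3, pool_len = 2,
                            spatial_dropout_rate = 0)
  m <- build_member(cfg, c(12, 5), 2)
  set.seed(6)
  x <- array(runif(1 * 12 * 5), dim = c(1, 12, 5))
  f0 <- member_features(m, x)
  # permuting input channels together with their kernels permutes features
  perm <- c(3, 5, 1, 4, 2)
  mp <- m
  mp$params$conv_w <- m$params$conv_w[, perm]
  mp$params$conv_b <- m$params$conv_b[perm]
  mp$params$gamma <- m$params$gamma[perm]
  mp$params$beta <- m$params$beta[perm]
  mp$state$running_mean <- m$state$running_mean[perm]
  mp$state$running_var <- m$state$running_var[perm]
  fp <- member_features(mp, x[, , perm, drop = FALSE])
  expect_equal(fp$conv, f0$conv[, , perm, drop = FALSE])
  # zeroing one channel changes only that channel's features
  x2 <- x
  x2[, , 2] <- 0
  f2 <- member_features(m, x2)
  expect_equal(f2$conv[, , -2], f0$conv[, , -2])
  expect_false(isTRUE(all.equal(f2$conv[, , 2], f0$conv[, , 2])))
})

test_that("inference is deterministic (dropout inactive)", {
  m <- build_member(tiny_member_config(spatial_dropout_rate = 0.5), c(10, 4), 2)
  set.seed(8)
  x <- array(runif(3 * 10 * 4), dim = c(3, 10, 4))
  model <- structure(list(members = list(m), n_classes = 2L,
                          input_shape = c(10L, 4L), class_order = c("A", "B")),
                     class = "lcmsnet_ensemble")
  p1 <- predict_proba(model, x)
  p2 <- predict_proba(model, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-6)
})

test_that("ensemble probabilities are the mean over members", {
  cfg <- tiny_member_config(spatial_dropout_rate = 0)
  m1 <- build_member(cfg, c(10, 4), 2)
  m2 <- build_member(tiny_member_config(seed = 99, spatial_dropout_rate = 0),
                     c(10, 4), 2)
  model2 <- structure(list(members = list(m1, m2), n_classes = 2L,
                           input_shape = c(10L, 4L), class_order = c("A", "B")),
                      class = "lcmsnet_ensemble")
  model1 <- structure(list(members = list(m1), n_classes = 2L,
                           input_shape = c(10L, 4L), class_order = c("A", "B")),
                      class = "lcmsnet_ensemble")
  set.seed(9)
  x <- array(runif(4 * 10 * 4), dim = c(4, 10, 4))
  pa <- predict_proba(model1, x)
  pb <- predict_proba(structure(list(members = list(m2), n_classes = 2L,
                                     input_shape = c(10L, 4L),
                                     class_order = c("A", "B")),
                                class = "lcmsnet_ensemble"), x)
  pm <- predict_proba(model2, x)
  expect_equal(pm, (pa + pb) / 2)
  # shape mismatch is rejected
  expect_error(predict_proba(model1, array(0, dim = c(1, 9, 4))),
               class = "lcmsnet_shape_error")
})

test_that("parameter counting matches a hand count and scales with size", {
  # 2 channels, 3-tap kernels, pool 2 over T=8 -> Tout=6, J=3, F=6 features
  cfg <- tiny_member_config(kernel_len = 3, pool_len = 2)
  m <- build_member(cfg, c(8, 2), 2)
  hand <- (2 + 2) +            # batch-norm gamma, beta
    (3 * 2 + 2) +              # depthwise kernels + bias
    (6 * 2 + 2)                # dense weights + bias
  expect_equal(count_parameters(m), hand)
  bigger <- build_member(cfg, c(16, 2), 2)   # longer RT -> more dense inputs
  expect_gt(count_parameters(bigger), count_parameters(m))
})

test_that("training separates a linearly separable two-class fixture", {
  imgs <- separable_images(n_per_class = 12)
  model <- train_ensemble(imgs, n_members = 1, config = tiny_member_config())
  expect_identical(model$class_order, c("A", "B"))
  probs <- predict_proba(model, imgs)
  pred <- model$class_order[apply(probs, 1, which.max)]
  truth <- vapply(imgs, `[[`, character(1), "label")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  imgs <- separable_images(n_per_class = 6)
  cfg <- tiny_member_config(max_epochs = 4)
  m1 <- train_ensemble(imgs, n_members = 2, config = cfg)
  m2 <- train_ensemble(imgs, n_members = 2, config = cfg)
  expect_identical(lapply(m1$members, `[[`, "params"),
                   lapply(m2$members, `[[`, "params"))
})

test_that("ensemble log-loss never exceeds the worst member's", {
  imgs <- separable_images(n_per_class = 8, seed = 3)
  truth <- vapply(imgs, `[[`, character(1), "label")
  model <- train_ensemble(imgs, n_members = 3,
                          config = tiny_member_config(max_epochs = 5))
  y <- match(truth, model$class_order)
  ll <- function(p) -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12)))
  member_ll <- vapply(model$members, function(m) {
    sub <- structure(list(members = list(m), n_classes = model$n_classes,
                          input_shape = model$input_shape,
                          class_order = model$class_order),
                     class = "lcmsnet_ensemble")
    ll(predict_proba(sub, imgs))
  }, numeric(1))
  expect_lte(ll(predict_proba(model, imgs)), max(member_ll) + 1e-9)
})

test_that("training requires at least two classes present", {
  imgs <- separable_images(n_per_class = 4)
  labs <- rep("A", length(imgs))
  expect_error(train_ensemble(imgs, labels = labs, n_members = 1,
                              config = tiny_member_config()),
               class = "lcmsnet_parameter_error")
})

test_that("augmentation-trained models tolerate shifts up to max_shift", {
  cfg <- sim_config(n_classes = 2, samples_per_class = 20, n_markers = 6,
                    n_shared = 2, scan_interval = 5, acquisition_span = 300,
                    mz_span = c(100, 300), rt_drift_sd = 0, height_cv = 0.2,
                    n_background = 40, seed = 19)
  ds <- simulate_dataset(cfg)
  grid <- build_uniform_grid(c(0, 300), 5, c(100, 300), 4)
  labs <- sample_labels(ds)
  sp <- stratified_split(labs, 0.25, seed = 2)
  train <- augment_dataset(ds[sp == "train"],
                           augment_config(max_shift = 10, copies_per_sample = 2,
                                          seed = 3))
  model <- train_ensemble(bin_dataset(train, grid), n_members = 1,
                          config = member_config(kernel_len = 3, pool_len = 4,
                                                 max_epochs = 12, batch_size = 8,
                                                 learning_rate = 5e-3, seed = 7))
  test <- ds[sp == "test"]
  acc_at <- function(delta) {
    shifted <- lapply(test, shift_rt, delta = delta)
    probs <- predict_proba(model, bin_dataset(shifted, grid))
    pred <- model$class_order[apply(probs, 1, which.max)]
    mean(pred == sample_labels(test))
  }
  a0 <- acc_at(0)
  small <- mean(c(acc_at(8), acc_at(-8)))   # within the augmented range
  large <- mean(c(acc_at(24), acc_at(-24))) # ~3x the augmented range
  expect_lt(a0 - small, a0 - large)
  expect_gte(small, 0.7)
})
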