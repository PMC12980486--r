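#' Configuration of one ensemble member
#'
#' Architecture and optimization knobs of a single depthwise 1D-CNN
#' member: input batch normalization per m/z channel, a depthwise
#' convolution of `kernel_len` taps along the RT axis (one independent
#' kernel per m/z channel, no cross-channel mixing), non-overlapping max
#' pooling of window `pool_len` along RT, spatial dropout of whole m/z
#' channels, then flatten and a dense softmax layer with an L1 penalty on
#' its weights.
#'
#' @param kernel_len RT taps per depthwise filter (>= 1).
#' @param pool_len max-pool window along RT (>= 1, stride = window).
#' @param spatial_dropout_rate probability of dropping an entire m/z
#'   channel during training, in `[0, 1)`.
#' @param l1_coeff L1 penalty weight on the dense-layer weights.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights are restored).
#' @param val_fraction fraction of the training data held out, stratified,
#'   for early stopping.
#' @param seed integer seed; member k of an ensemble derives its own seed
#'   from this.
#' @return A list of class `member_config`.
#' @export
member_config <- function(kernel_len = 7, pool_len = 8,
                          spatial_dropout_rate = 0.2, l1_coeff = 1e-5,
                          learning_rate = 1e-3, batch_size = 32,
                          max_epochs = 30, early_stop_patience = 4,
                          val_fraction = 0.1, seed = 1) {
  check_number(kernel_len, "kernel_len", lower = 1)
  check_number(pool_len, "pool_len", lower = 1)
  check_number(spatial_dropout_rate, "spatial_dropout_rate", lower = 0, upper = 1 - 1e-9)
  check_number(l1_coeff, "l1_coeff", lower = 0)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  structure(list(kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len),
                 spatial_dropout_rate = spatial_dropout_rate,
                 l1_coeff = l1_coeff, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "member_config")
}

#' Build an untrained ensemble member
#'
#' Initializes the member's parameters (batch-norm affine terms, depthwise
#' kernels, dense layer) for a given input shape, deterministically under
#' the config seed.
#'
#' @param config a [member_config()].
#' @param input_shape integer length-2 `(n_rt, n_mz)`.
#' @param n_classes number of output classes (>= 2).
#' @return A list of class `lcmsnet_member` with `params` (gamma, beta,
#'   conv_w, conv_b, dense_w, dense_b) and `state` (running batch-norm
#'   statistics).
#' @export
build_member <- function(config, input_shape, n_classes) {
  if (n_classes < 2) abort_lcms("n_classes must be >= 2", "lcmsnet_parameter_error")
  TT <- as.integer(input_shape[1]); C <- as.integer(input_shape[2])
  L <- config$kernel_len; P <- config$pool_len
  if (L > TT) abort_lcms("kernel_len exceeds the number of RT bins", "lcmsnet_parameter_error")
  Tout <- TT - L + 1L
  if (P > Tout) abort_lcms("pool_len exceeds the convolved RT length", "lcmsnet_parameter_error")
  J <- Tout %/% P
  Fdim <- J * C
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  lim <- sqrt(6 / (Fdim + n_classes))
  params <- list(
    gamma = rep(1, C), beta = rep(0, C),
    conv_w = matrix(stats::rnorm(L * C, 0, sqrt(2 / L)), L, C),
    conv_b = rep(0, C),
    dense_w = matrix(stats::runif(Fdim * n_classes, -lim, lim), Fdim, n_classes),
    dense_b = rep(0, n_classes)
  )
  structure(list(config = config, input_shape = c(TT, C),
                 n_classes = as.integer(n_classes), params = params,
                 state = list(running_mean = rep(0, C), running_var = rep(1, C)),
                 trained = FALSE, history = NULL),
            class = "lcmsnet_member")
}

# Forward a member on a channel-first (C, N, T) array in chunks; inference.
member_predict <- function(member, Xc, chunk = 256L) {
  N <- dim(Xc)[2]
  out <- matrix(0, N, member$n_classes)
  i <- 1L
  while (i <= N) {
    j <- min(i + chunk - 1L, N)
    fwd <- nn_forward(member$params, member$state, member$config,
                      Xc[, i:j, , drop = FALSE], member$n_classes)
    out[i:j, ] <- fwd$probs
    i <- j + 1L
  }
  out
}

#' Intermediate feature maps of a member
#'
#' Runs a member in inference mode and returns the normalized input, the
#' depthwise convolution output and the pooled (pre-dropout) feature map,
#' mainly for inspection and testing of the architecture contract.
#'
#' @param member an `lcmsnet_member`.
#' @param x a pseudoimage, list of pseudoimages, or `(N, T, C)` array.
#' @return List with arrays `bn`, `conv`, `pool` and matrix `probs`.
#' @export
member_features <- function(member, x) {
  Xc <- to_channel_first(images_to_array(x))
  fwd <- nn_forward(member$params, member$state, member$config, Xc,
                    member$n_classes, keep_features = TRUE)
  feats <- lapply(fwd$features, function(a) aperm(a, c(2, 3, 1)))
  c(feats, list(probs = fwd$probs))
}

# Train one member with Adam, minibatches, an own stratified validation
# split for early stopping, and restoration of the best weights.
train_member <- function(member, X, y_idx, verbose = FALSE) {
  cfg <- member$config
  N <- dim(X)[2]                         # X is channel-first (C, N, T)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 401))

  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    sp <- stratified_split(as.character(y_idx), test_fraction = cfg$val_fraction,
                           seed = derive_seed(cfg$seed, 402))
    val_idx <- which(sp == "test")
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  Xval <- X[, val_idx, , drop = FALSE]
  yval <- y_idx[val_idx]

  opt <- adam_init(member$params)
  best <- list(loss = Inf, params = member$params, state = member$state)
  wait <- 0L
  momentum <- 0.9
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + cfg$batch_size - 1L, length(ord))
      bi <- ord[i:j]
      Xb <- X[, bi, , drop = FALSE]
      fwd <- nn_forward(member$params, member$state, cfg, Xb,
                        member$n_classes, training = TRUE, keep_cache = TRUE)
      member$state$running_mean <- momentum * member$state$running_mean +
        (1 - momentum) * fwd$batch_mu
      member$state$running_var <- momentum * member$state$running_var +
        (1 - momentum) * fwd$batch_var
      g <- nn_backward(member$params, cfg, fwd, y_idx[bi], member$n_classes)
      st <- adam_step(member$params, g, opt, cfg$learning_rate)
      member$params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + nn_loss(fwd$probs, y_idx[bi], member$params$dense_w,
                                   cfg$l1_coeff)
      nb <- nb + 1L
      i <- j + 1L
    }
    val_loss <- if (length(val_idx)) {
      pv <- member_predict(member, Xval)
      nn_loss(pv, yval, member$params$dense_w, 0)
    } else ep_loss / nb
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("  epoch %2d: train %.4f  val %.4f", epoch,
                      ep_loss / nb, val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = member$params, state = member$state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  member$params <- best$params
  member$state <- best$state
  member$trained <- TRUE
  member$history <- history
  member
}

#' Train a depthwise 1D-CNN ensemble
#'
#' Trains `n_members` members on the (optionally class-balanced) training
#' images. Each member gets a distinct seed-derived initialization and its
#' own stratified validation split for early stopping; predictions of the
#' ensemble are the arithmetic mean of the members' class probabilities.
#'
#' @param x list of `pseudoimage`s (or an `(N, T, C)` array).
#' @param labels character vector of class labels (ignored if `x` is a
#'   list of labeled pseudoimages and `labels` is `NULL`).
#' @param n_members ensemble size K (>= 1; default 5).
#' @param config a [member_config()] shared by all members.
#' @param oversample_classes balance classes by random oversampling before
#'   training (default `TRUE`).
#' @param verbose print per-epoch losses.
#' @return A list of class `lcmsnet_ensemble` with fields `members`,
#'   `n_classes`, `input_shape`, `class_order` (sorted unique labels).
#' @export
train_ensemble <- function(x, labels = NULL, n_members = 5,
                           config = member_config(),
                           oversample_classes = TRUE, verbose = FALSE) {
  if (is.null(labels)) {
    labels <- vapply(x, function(im) as.character(im$label), character(1))
  }
  if (any(is.na(labels))) {
    abort_lcms("all training samples must be labeled", "lcmsnet_parameter_error")
  }
  class_order <- sort(unique(labels))
  if (length(class_order) < 2) {
    abort_lcms("at least 2 classes must be present in the training data",
               "lcmsnet_parameter_error")
  }
  X <- to_channel_first(images_to_array(x))
  if (oversample_classes) {
    idx <- attr(oversample(as.list(seq_along(labels)), labels = labels,
                           seed = derive_seed(config$seed, 403)), "index")
    X <- X[, idx, , drop = FALSE]
    labels <- labels[idx]
  }
  y_idx <- match(labels, class_order)
  input_shape <- dim(X)[c(3, 1)]         # (n_rt, n_mz)
  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, c(500, k))
    if (verbose) message(sprintf("training member %d/%d", k, n_members))
    m <- build_member(cfg_k, input_shape, length(class_order))
    members[[k]] <- train_member(m, X, y_idx, verbose = verbose)
  }
  structure(list(members = members, n_classes = length(class_order),
                 input_shape = input_shape, class_order = class_order,
                 config = config),
            class = "lcmsnet_ensemble")
}

#' @export
print.lcmsnet_ensemble <- function(x, ...) {
  cat(sprintf("<lcmsnet_ensemble> K=%d members, input %d x %d, classes: %s\n",
              length(x$members), x$input_shape[1], x$input_shape[2],
              paste(x$class_order, collapse = ", ")))
  cat(sprintf("  trainable parameters: %d total\n", count_parameters(x)))
  invisible(x)
}

#' Ensemble class probabilities
#'
#' Arithmetic mean of the members' softmax outputs, in inference mode
#' (running batch-norm statistics, dropout inactive); rows sum to 1.
#'
#' @param model an `lcmsnet_ensemble`.
#' @param x a pseudoimage, list of pseudoimages, or `(N, T, C)` array whose
#'   shape matches `model$input_shape`.
#' @return Numeric matrix `N x n_classes` with columns named by
#'   `model$class_order` (a single pseudoimage yields a 1-row matrix).
#' @export
predict_proba <- function(model, x) {
  X <- images_to_array(x)
  if (!identical(as.integer(dim(X)[2:3]), as.integer(model$input_shape))) {
    abort_lcms(sprintf("input shape (%d, %d) does not match model input (%d, %d)",
                       dim(X)[2], dim(X)[3],
                       model$input_shape[1], model$input_shape[2]),
               "lcmsnet_shape_error")
  }
  Xc <- to_channel_first(X)
  acc <- matrix(0, dim(X)[1], model$n_classes)
  for (m in model$members) acc <- acc + member_predict(m, Xc)
  probs <- acc / length(model$members)
  colnames(probs) <- model$class_order
  ids <- if (is.list(x) && !is.array(x)) {
    vapply(x, function(im) if (!is.null(im$sample_id)) im$sample_id else NA_character_,
           character(1))
  } else if (inherits(x, "pseudoimage")) x$sample_id else NULL
  if (!is.null(ids) && !anyNA(ids)) rownames(probs) <- ids
  probs
}

#' Count trainable parameters
#'
#' Sums all trainable weights: batch-norm affine terms, depthwise kernels
#' and biases, and the dense layer, per member and over the ensemble.
#' Running batch-norm statistics are not trainable and are not counted.
#'
#' @param model an `lcmsnet_ensemble` or a single `lcmsnet_member`.
#' @param per_member return the per-member count instead of the total.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, per_member = FALSE) {
  one <- function(m) sum(vapply(m$params, length, numeric(1)))
  if (inherits(model, "lcmsnet_member")) return(one(model))
  counts <- vapply(model$members, one, numeric(1))
  if (per_member) counts else sum(counts)
}

#' Save / load a trained ensemble
#'
#' The archive holds the member weights, configs, class order and (when
#' supplied at save time) the bin grid used to produce the inputs.
#'
#' @param model an `lcmsnet_ensemble`.
#' @param path file path for the archive.
#' @param grid optional `bin_grid` stored alongside the model.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   ensemble (with attribute `"grid"` when one was stored).
#' @export
save_model <- function(model, path, grid = NULL) {
  if (!is.null(grid)) attr(model, "grid") <- grid
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
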