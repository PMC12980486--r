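# Internal layer math for the depthwise 1D-CNN member.
#
# Public arrays are (batch N, time T, channel C); internally tensors are
# channel-first (C, B, T) so that per-channel vectors broadcast along the
# fastest axis for free and the compiled depthwise kernels see contiguous
# time planes. The hot loops (depthwise convolution, max pooling) are in
# src/depthwise.cpp.

bn_eps <- 1e-5

# Stack a list of pseudoimages (T x C matrices) into an (N, T, C) array.
images_to_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) return(images)
  if (inherits(images, "pseudoimage")) images <- list(images)
  mats <- lapply(images, function(im) if (inherits(im, "pseudoimage")) im$values else im)
  d <- dim(mats[[1]])
  X <- array(0, dim = c(length(mats), d[1], d[2]))
  for (i in seq_along(mats)) {
    if (!identical(dim(mats[[i]]), d)) {
      abort_lcms("pseudoimages have inconsistent shapes", "lcmsnet_shape_error")
    }
    X[i, , ] <- mats[[i]]
  }
  X
}

# (N, T, C) -> channel-first (C, N, T)
to_channel_first <- function(X) aperm(X, c(3, 1, 2))

# Forward pass on a channel-first batch Xc (C, B, T). Returns probs plus
# the caches needed for the backward pass when `keep_cache = TRUE`.
nn_forward <- function(params, state, cfg, Xc, n_classes,
                       training = FALSE, keep_cache = FALSE,
                       keep_features = FALSE) {
  d <- dim(Xc); C <- d[1]; B <- d[2]; TT <- d[3]
  L <- cfg$kernel_len; P <- cfg$pool_len
  Tout <- TT - L + 1L
  J <- Tout %/% P

  # --- input batch normalization, per m/z channel over (batch, time)
  if (training) {
    mu <- rowMeans(Xc, dims = 1)
    Xcent <- Xc - mu
    va <- rowMeans(Xcent * Xcent, dims = 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    Xcent <- Xc - mu
  }
  inv <- 1 / sqrt(va + bn_eps)
  Xhat <- Xcent * inv
  Z <- Xhat * params$gamma + params$beta

  # --- depthwise 1D convolution along RT (valid), one kernel per channel
  Y <- .dw_conv_forward(Z, params$conv_w, params$conv_b, C, B, TT)
  dim(Y) <- c(C, B, Tout)

  # --- max pooling along RT, window P, stride P (remainder dropped)
  pool <- .dw_maxpool_forward(Y, C, B, Tout, P)
  M <- pool$M
  dim(M) <- c(C, B, J)

  # --- spatial dropout: whole m/z channels, per sample (training only)
  drop_mask <- NULL
  D <- M
  if (training && cfg$spatial_dropout_rate > 0) {
    drop_mask <- matrix(
      stats::rbinom(C * B, 1L, 1 - cfg$spatial_dropout_rate), C, B
    ) / (1 - cfg$spatial_dropout_rate)
    D <- M * as.vector(drop_mask)        # recycles over pooled time
  }

  # --- flatten (features ordered (channel, pooled-time)) + dense softmax
  Fm <- aperm(D, c(1, 3, 2))
  dim(Fm) <- c(C * J, B)
  logits <- crossprod(Fm, params$dense_w) +
    matrix(params$dense_b, B, n_classes, byrow = TRUE)
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  probs <- el / rowSums(el)

  out <- list(probs = probs, batch_mu = mu, batch_var = va)
  if (keep_cache) {
    out$cache <- list(C = C, B = B, TT = TT, Tout = Tout, J = J, P = P,
                      Xhat = Xhat, Z = Z, A = pool$argmax,
                      drop_mask = drop_mask, Fm = Fm)
  }
  if (keep_features) out$features <- list(bn = Z, conv = Y, pool = M)
  out
}

# Backward pass for mean cross-entropy + L1 on the dense weights.
# y_idx: integer class indices in 1..n_classes. Returns gradient list.
nn_backward <- function(params, cfg, fwd, y_idx, n_classes) {
  cc <- fwd$cache
  C <- cc$C; B <- cc$B; J <- cc$J

  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits / B

  g <- list()
  g$dense_w <- cc$Fm %*% dlogits + cfg$l1_coeff * sign(params$dense_w)
  g$dense_b <- colSums(dlogits)

  dFm <- params$dense_w %*% t(dlogits)
  dim(dFm) <- c(C, J, B)
  dD <- aperm(dFm, c(1, 3, 2))           # back to (C, B, J)
  if (!is.null(cc$drop_mask)) dD <- dD * as.vector(cc$drop_mask)

  dY <- .dw_maxpool_backward(dD, cc$A, C, B, cc$Tout, cc$P)
  cb <- .dw_conv_backward(dY, cc$Z, params$conv_w, C, B, cc$TT)
  g$conv_w <- cb$dw
  g$conv_b <- cb$db

  dZ <- cb$dZ
  dim(dZ) <- c(C, B, cc$TT)
  # batch-norm affine parameters (input gradient not needed: first layer)
  g$gamma <- rowSums(dZ * cc$Xhat, dims = 1)
  g$beta <- rowSums(dZ, dims = 1)
  g
}

nn_loss <- function(probs, y_idx, dense_w, l1_coeff) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)
  mean(-log(p)) + l1_coeff * sum(abs(dense_w))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
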