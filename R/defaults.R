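#' Default full-scale m/z density prior
#'
#' The shipped default prior for a Q-TOF metabolomics acquisition over
#' m/z 50-1000: the metabolite-dense region below 500 Th gets fine
#' 0.5 Th bins, the sparser high-mass region broad 1 Th bins (900 + 500 =
#' 1400 m/z channels). Study-specific priors can be estimated from data
#' with [estimate_density_prior()] or supplied explicitly.
#'
#' @return A [density_prior()].
#' @export
default_density_prior <- function() {
  density_prior(data.frame(mz_lo = c(50, 500), mz_hi = c(500, 1000),
                           bin_width = c(0.5, 1.0)))
}

#' Default full-scale bin grid
#'
#' Adaptive grid for a 12-minute (720 s) acquisition sampled once per
#' second: 720 RT bins matching the scan interval and the 1400 m/z
#' channels of [default_density_prior()].
#'
#' @return A `bin_grid`.
#' @export
default_grid <- function() {
  build_adaptive_grid(c(0, 720), acquisition_interval = 1,
                      prior = default_density_prior())
}

#' Default full-scale member configuration
#'
#' Architecture defaults for the full 720 x 1400 input grid: 9-tap
#' depthwise kernels (smooths over ~9 s of retention time), max-pool
#' windows of 64 RT bins (the pooled features approximate the strongest
#' signal per m/z channel per gradient segment), 20% spatial dropout and a
#' light L1 penalty. With K = 5 members the ensemble stays under half a
#' million trainable parameters.
#'
#' @param ... overrides passed to [member_config()].
#' @return A [member_config()].
#' @export
default_member_config <- function(...) {
  args <- utils::modifyList(
    list(kernel_len = 9, pool_len = 64, spatial_dropout_rate = 0.2,
         l1_coeff = 1e-5, learning_rate = 1e-3, batch_size = 32,
         max_epochs = 50, early_stop_patience = 5, val_fraction = 0.1,
         seed = 1),
    list(...)
  )
  do.call(member_config, args)
}

#' Default full-scale (untrained) ensemble
#'
#' Instantiates the default K = 5 ensemble for the default grid and five
#' classes without training it, e.g. to inspect the architecture or count
#' trainable parameters.
#'
#' @param n_classes number of classes (default 5).
#' @param n_members ensemble size (default 5).
#' @param config member configuration (default [default_member_config()]).
#' @param grid bin grid defining the input shape (default [default_grid()]).
#' @return An `lcmsnet_ensemble` with untrained members.
#' @export
default_ensemble <- function(n_classes = 5, n_members = 5,
                             config = default_member_config(),
                             grid = default_grid()) {
  input_shape <- c(length(grid$rt_edges) - 1L, length(grid$mz_edges) - 1L)
  members <- lapply(seq_len(n_members), function(k) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, c(500, k))
    build_member(cfg_k, input_shape, n_classes)
  })
  structure(list(members = members, n_classes = as.integer(n_classes),
                 input_shape = input_shape,
                 class_order = sprintf("class%02d", seq_len(n_classes)),
                 config = config),
            class = "lcmsnet_ensemble")
}
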