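#' @keywords internal
#' @useDynLib lcmsnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Deterministic seed fan-out: one user-facing seed spawns independent
# per-stage / per-sample seeds via a fixed LCG-style mix, kept < 2^31.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(tag))
  s <- (as.double(seed) %% 2147483629) + 1
  for (t in as.double(tag)) {
    s <- (s * 48271 + t + 1) %% 2147483629
  }
  as.integer(s)
}

abort_lcms <- function(msg, class) {
  stop(structure(
    class = c(class, "lcmsnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_lcms(sprintf("`%s` must be a single number", name), "lcmsnet_parameter_error")
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    abort_lcms(sprintf("`%s` = %g is out of range", name, x), "lcmsnet_parameter_error")
  }
  invisible(x)
}
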