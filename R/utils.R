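# Internal validation helpers shared across modules.

abort_leafspad <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "leafspad_error"), ...)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_leafspad(sprintf("`%s` must be a single finite number.", name),
                   "leafspad_parameter_error")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort_leafspad(sprintf("`%s` = %g is out of range [%g, %g].",
                           name, x, lower, upper),
                   "leafspad_parameter_error")
  }
  invisible(x)
}

check_image <- function(img, name = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort_leafspad(sprintf("`%s` must be an H x W x 3 array.", name),
                   "leafspad_parameter_error")
  }
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255) {
    abort_leafspad(sprintf("`%s` must contain intensities in [0, 255].", name),
                   "leafspad_parameter_error")
  }
  invisible(img)
}

check_matrix_numeric <- function(X, name = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort_leafspad(sprintf("`%s` must be a numeric matrix with finite values.",
                           name), "leafspad_validation_error")
  }
  X
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards; all stochastic code paths go through this.
with_seed_ls <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}
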