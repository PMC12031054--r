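# Shared kernel evaluations for SVR and RVM.
# gamma follows the exp(-gamma * ||x - x'||^2) convention for "rbf"/"gaussian".
kernel_matrix <- function(X1, X2, kernel, gamma = NULL, degree = 3,
                          coef0 = 0) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  switch(kernel,
    linear = X1 %*% t(X2),
    rbf = ,
    gaussian = {
      d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
      exp(-gamma * pmax(d2, 0))
    },
    poly = (gamma * (X1 %*% t(X2)) + coef0)^degree,
    abort_leafspad(sprintf("Unknown kernel '%s'.", kernel),
                   "leafspad_parameter_error")
  )
}

#' Support vector regression configuration
#'
#' Defaults follow the study configuration for SPAD prediction: a linear
#' kernel with penalty `C = 0.01` and tube half-width `epsilon = 0.1` (small
#' relative to the SPAD standard deviation of about 6). `gamma` (150 in the
#' study printout) is stored for fidelity but has no mathematical effect
#' under a linear kernel; an informational message notes this at fit time.
#'
#' @param C Positive penalty parameter balancing flatness against slack.
#' @param epsilon Non-negative half-width of the insensitive tube.
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param gamma Kernel width for rbf/poly (inert for linear).
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(C = 0.01, epsilon = 0.1,
                       kernel = c("linear", "rbf", "poly"), gamma = 150) {
  kernel <- match.arg(kernel)
  check_scalar_number(C, "C", lower = 1e-12)
  check_scalar_number(epsilon, "epsilon", lower = 0)
  check_scalar_number(gamma, "gamma", lower = 1e-12)
  structure(list(C = C, epsilon = epsilon, kernel = kernel, gamma = gamma),
            class = "svr_config")
}

#' Fit epsilon-insensitive support vector regression
#'
#' Minimizes \eqn{\tfrac12\|\omega\|^2 + C\sum_i(\xi_i + \xi_i^*)} subject
#' to all residuals lying within the \eqn{\varepsilon}-tube up to the slack
#' variables. The quadratic program is solved by libsvm (via
#' \pkg{e1071}) at a tight termination tolerance; the returned model stores
#' the dual coefficients, the bias, and the support vectors, and predictions
#' depend on the support vectors alone.
#'
#' @param X n x k numeric matrix of inputs.
#' @param y Numeric response vector of length n.
#' @param config An [svr_config()].
#' @return Object of class `svr_model`.
#' @export
fit_svr <- function(X, y, config = svr_config()) {
  X <- check_matrix_numeric(X)
  if (length(y) != nrow(X) || any(!is.finite(y))) {
    abort_leafspad("`y` must be finite and match the rows of `X`.",
                   "leafspad_validation_error")
  }
  if (nrow(X) < 2L) {
    abort_leafspad("SVR needs at least two training samples.",
                   "leafspad_validation_error")
  }
  if (config$kernel == "linear" && !is.null(config$gamma)) {
    rlang::inform(
      "gamma is stored but has no effect under a linear kernel.",
      class = "leafspad_inert_gamma",
      .frequency = "once", .frequency_id = "leafspad_inert_gamma")
  }
  fit <- tryCatch(
    e1071::svm(
      x = X, y = y, type = "eps-regression", scale = FALSE,
      kernel = switch(config$kernel, linear = "linear", rbf = "radial",
                      poly = "polynomial"),
      cost = config$C, epsilon = config$epsilon, gamma = config$gamma,
      tolerance = 1e-7),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop(e)
    })
  if (is.null(fit)) {
    # every residual fits inside the tube with w = 0: no support vectors,
    # bias at the midrange (the analytic optimum of the degenerate problem)
    fit <- list(index = integer(0), coefs = numeric(0),
                rho = -mean(range(y)))
  }
  structure(list(
    config = config,
    dual_coefs = as.numeric(fit$coefs),
    support_index = fit$index,
    support_vectors = X[fit$index, , drop = FALSE],
    bias = -fit$rho,
    n_features = ncol(X),
    n_train = nrow(X)
  ), class = "svr_model")
}

#' Predict from a fitted SVR model
#'
#' Kernel expansion over the stored support vectors:
#' \eqn{f(x) = \sum_i \beta_i K(x_i, x) + b}.
#'
#' @param object An `svr_model`.
#' @param newdata m x k matrix with the training feature count.
#' @param ... Unused.
#' @return Numeric vector of m predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != object$n_features) {
    abort_leafspad(sprintf("Model expects %d features, got %d.",
                           object$n_features, ncol(X)),
                   "leafspad_schema_error")
  }
  K <- kernel_matrix(X, object$support_vectors, object$config$kernel,
                     gamma = object$config$gamma)
  drop(K %*% object$dual_coefs + object$bias)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "<svr_model> %s kernel, C = %g, epsilon = %g, %d/%d support vectors\n",
    x$config$kernel, x$config$C, x$config$epsilon,
    length(x$dual_coefs), x$n_train))
  invisible(x)
}

#' @export
tidy.svr_model <- function(x, ...) {
  tibble::tibble(support_index = x$support_index,
                 dual_coef = x$dual_coefs)
}

#' @export
glance.svr_model <- function(x, ...) {
  tibble::tibble(kernel = x$config$kernel, C = x$config$C,
                 epsilon = x$config$epsilon,
                 n_support = length(x$dual_coefs), n_train = x$n_train,
                 bias = x$bias)
}

#' Serialize / restore an SVR model as JSON
#' @param object An `svr_model`.
#' @param path JSON path.
#' @export
write_svr <- function(object, path) {
  payload <- list(
    schema = "leafspad/svr/1",
    config = unclass(object$config),
    dual_coefs = object$dual_coefs,
    support_index = object$support_index,
    support_vectors = unname(object$support_vectors),
    bias = object$bias, n_features = object$n_features,
    n_train = object$n_train
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svr
#' @export
read_svr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- p$support_vectors
  if (!is.matrix(sv)) sv <- matrix(unlist(sv), ncol = p$n_features,
                                   byrow = TRUE)
  structure(list(
    config = structure(p$config, class = "svr_config"),
    dual_coefs = p$dual_coefs,
    support_index = as.integer(p$support_index),
    support_vectors = sv,
    bias = p$bias,
    n_features = as.integer(p$n_features),
    n_train = as.integer(p$n_train)
  ), class = "svr_model")
}
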