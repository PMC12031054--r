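#' Fit a staged CNN + kernel-regressor hybrid
#'
#' Stage 1 trains the convolutional network on `(X, y)` (two conv blocks by
#' default, 3x16 then 2x32). Stage 2 freezes it, extracts the activations
#' of the tap layer (default `"pool2"`, falling back to the last pooling
#' layer) for every training row, and fits the downstream regressor on
#' those features: epsilon-SVR (linear kernel, C = 0.01 by default) for
#' CNN-SVR, or a Gaussian-kernel RVM with `gamma = 0.05` for CNN-RVM.
#' Prediction composes the two stages.
#'
#' @param X n x k numeric matrix.
#' @param y Numeric response of length n.
#' @param downstream `"svr"` or `"rvm"`.
#' @param arch A [cnn_architecture()]; default [cnn_architecture_hybrid()].
#' @param cfg A [cnn_train_config()].
#' @param tap Tap layer name, or `NULL` for the default.
#' @param svr An [svr_config()] for the downstream SVR.
#' @param rvm_gamma,rvm_kernel Downstream RVM kernel settings.
#' @param X_val,y_val Optional validation split for the CNN's early
#'   stopping.
#' @return Object of class `hybrid_model` holding the trained `cnn`, the
#'   `tap` name and the fitted `downstream` model.
#' @export
fit_hybrid <- function(X, y, downstream = c("svr", "rvm"),
                       arch = cnn_architecture_hybrid(),
                       cfg = cnn_train_config(),
                       tap = NULL,
                       svr = svr_config(),
                       rvm_gamma = 0.05, rvm_kernel = "gaussian",
                       X_val = NULL, y_val = NULL) {
  downstream <- match.arg(downstream)
  cnn <- train_cnn(X, y, arch = arch, cfg = cfg,
                   X_val = X_val, y_val = y_val)
  if (is.null(tap)) {
    pools <- grep("^pool", arch$layer_names, value = TRUE)
    tap <- if ("pool2" %in% pools) "pool2" else
      if (length(pools)) pools[length(pools)] else "relu_fc"
  }
  feats <- extract_features(cnn, X, tap = tap)
  reg <- if (downstream == "svr") {
    fit_svr(feats, y, config = svr)
  } else {
    fit_rvm(feats, y, kernel = rvm_kernel, gamma = rvm_gamma)
  }
  structure(list(cnn = cnn, tap = tap, type = downstream,
                 downstream = reg),
            class = "hybrid_model")
}

#' Predict from a CNN + kernel-regressor hybrid
#' @param object A `hybrid_model`.
#' @param newdata m x k matrix on the CNN input scale.
#' @param ... Unused.
#' @return Numeric vector of m predictions.
#' @export
predict.hybrid_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  feats <- extract_features(object$cnn, X, tap = object$tap)
  p <- stats::predict(object$downstream, feats)
  if (is.data.frame(p)) p$mean else p
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> CNN (tap '%s') -> %s\n", x$tap,
              toupper(x$type)))
  print(x$cnn)
  print(x$downstream)
  invisible(x)
}

#' @export
glance.hybrid_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(type = paste0("cnn_", x$type), tap = x$tap),
    glance(x$cnn)[, c("epochs_run", "best_epoch")],
    n_basis = if (x$type == "svr") length(x$downstream$dual_coefs)
              else length(x$downstream$relevance_index)
  )
}
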