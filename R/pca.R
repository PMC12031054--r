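#' Fit a standardized principal component analysis
#'
#' Columns are standardized to zero mean and unit variance (the
#' standardization parameters are stored for later projection), and the
#' correlation matrix is eigendecomposed. The selected color indices live on
#' wildly different scales (raw channels near 100, ratio indices near 1), so
#' PCA on the correlation matrix, not the raw covariance, is the meaningful
#' choice here.
#'
#' The number of retained components is `n_components` when given (the
#' pipeline default is 5), otherwise the smallest k whose cumulative
#' explained-variance ratio reaches `variance_target`. Component signs are
#' fixed so the largest-magnitude loading of each component is positive,
#' making scores stable across runs and platforms. Eigenvalue ties are
#' broken by descending eigenvalue, then by the original index of the
#' peak-loading feature.
#'
#' @param X Numeric matrix or data frame (n samples x p features), no
#'   missing values.
#' @param n_components Fixed number of components to retain, or `NULL`.
#' @param variance_target Cumulative explained-variance target in (0, 1],
#'   used when `n_components` is `NULL` (default 0.9999).
#' @return Object of class `pca_model`: standardization means/sds, loading
#'   matrix (p x k, orthonormal columns), explained-variance ratios for all
#'   p components, retained `k`, feature names, and the training scores.
#' @export
fit_pca <- function(X, n_components = 5L, variance_target = 0.9999) {
  Xm <- check_matrix_numeric(X)
  if (is.null(colnames(Xm))) {
    colnames(Xm) <- paste0("V", seq_len(ncol(Xm)))
  }
  p <- ncol(Xm)
  means <- colMeans(Xm)
  sds <- apply(Xm, 2, stats::sd)
  zero_var <- sds <= .Machine$double.eps
  if (any(zero_var)) {
    abort_leafspad(paste0("Zero-variance column(s): ",
                          paste(colnames(Xm)[zero_var], collapse = ", ")),
                   "leafspad_validation_error")
  }
  Z <- scale(Xm, center = means, scale = sds)
  Cm <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(Cm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # tie-break equal eigenvalues by ascending index of the peak loading
  ord <- order(-vals, vapply(seq_len(p),
                             function(j) which.max(abs(vecs[, j])), 0L))
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(p)) {
    peak <- which.max(abs(vecs[, j]))
    if (vecs[peak, j] < 0) vecs[, j] <- -vecs[, j]
  }
  ratio <- vals / sum(vals)
  k <- if (!is.null(n_components)) {
    min(as.integer(n_components), p)
  } else {
    check_scalar_number(variance_target, "variance_target", 1e-12, 1)
    which(cumsum(ratio) >= variance_target - 1e-12)[1]
  }
  loadings <- vecs[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(Xm)
  colnames(loadings) <- paste0("PC", seq_len(k))
  model <- structure(list(
    feature_names = colnames(Xm),
    means = means, sds = sds,
    loadings = loadings,
    explained_variance_ratio = ratio,
    k = k
  ), class = "pca_model")
  model$scores <- stats::predict(model, Xm)
  model
}

#' Project new data onto fitted principal components
#'
#' Standardizes `newdata` with the training means/sds and projects onto the
#' retained loadings. Columns are matched by name and must all be present.
#'
#' @param object A `pca_model`.
#' @param newdata Matrix or data frame carrying the training feature columns.
#' @param ... Unused.
#' @return m x k score matrix with columns `PC1..PCk`.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$feature_names)) {
      abort_leafspad("Unnamed matrix with wrong column count.",
                     "leafspad_schema_error")
    }
    colnames(X) <- object$feature_names
  }
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing)) {
    abort_leafspad(paste0("Missing feature column(s): ",
                          paste(missing, collapse = ", ")),
                   "leafspad_schema_error")
  }
  X <- X[, object$feature_names, drop = FALSE]
  Z <- scale(X, center = object$means, scale = object$sds)
  Z %*% object$loadings
}

#' Reconstruct feature values from component scores
#'
#' Inverse of [predict.pca_model()]: back-projects scores and undoes the
#' standardization. Exact when all p components are retained.
#'
#' @param object A `pca_model`.
#' @param scores m x k score matrix.
#' @return m x p matrix on the original feature scale.
#' @export
inverse_pca <- function(object, scores) {
  Z <- scores %*% t(object$loadings)
  sweep(sweep(Z, 2, object$sds, `*`), 2, object$means, `+`)
}

#' @export
print.pca_model <- function(x, ...) {
  cum <- cumsum(x$explained_variance_ratio)
  cat(sprintf("<pca_model> %d features -> %d components (%.3f%% cumulative variance)\n",
              length(x$feature_names), x$k, 100 * cum[x$k]))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained_variance_ratio)),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_components = x$k,
    cumulative_variance = cumsum(x$explained_variance_ratio)[x$k]
  )
}

#' Scree plot of explained variance
#' @param object A `pca_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_model <- function(object, ...) {
  df <- tidy.pca_model(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained_variance_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1),
                       color = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative),
                        color = "firebrick") +
    ggplot2::labs(y = "Explained variance ratio", x = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize / restore a PCA model as JSON
#'
#' Stores standardization parameters, loadings, explained-variance ratios
#' and the retained component count under a versioned schema.
#'
#' @param object A `pca_model`.
#' @param path JSON path.
#' @return `write_pca()` returns `path` invisibly; `read_pca()` the model.
#' @export
write_pca <- function(object, path) {
  payload <- list(
    schema = "leafspad/pca/1",
    feature_names = object$feature_names,
    means = unname(object$means), sds = unname(object$sds),
    loadings = unname(object$loadings),
    explained_variance_ratio = object$explained_variance_ratio,
    k = object$k
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- if (is.matrix(p$loadings)) p$loadings else
    matrix(unlist(p$loadings), ncol = p$k, byrow = TRUE)
  rownames(loadings) <- p$feature_names
  colnames(loadings) <- paste0("PC", seq_len(p$k))
  structure(list(
    feature_names = p$feature_names,
    means = stats::setNames(p$means, p$feature_names),
    sds = stats::setNames(p$sds, p$feature_names),
    loadings = loadings,
    explained_variance_ratio = p$explained_variance_ratio,
    k = as.integer(p$k)
  ), class = "pca_model")
}
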