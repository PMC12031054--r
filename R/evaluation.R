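#' Root mean squared error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2}}.
#'
#' @param y_true,y_pred Numeric vectors of equal, nonzero length.
#' @return Non-negative number.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    abort_leafspad("`y_true` and `y_pred` must have equal, nonzero length.",
                   "leafspad_parameter_error")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2};
#' may be negative for predictions worse than the mean.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2); `y_true`
#'   must not be constant.
#' @return A number at most 1.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L) {
    abort_leafspad("`y_true` and `y_pred` must have equal length >= 2.",
                   "leafspad_parameter_error")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    abort_leafspad("R^2 undefined: `y_true` is constant.",
                   "leafspad_undefined_r2")
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Seeded 80/20 train/validation split
#'
#' @param n Number of samples (>= 5).
#' @param seed Integer seed.
#' @param val_fraction Validation share (default 0.2); the validation size
#'   is `round(val_fraction * n)`.
#' @return List with integer vectors `train` and `val`: disjoint,
#'   exhaustive, reproducible.
#' @export
split_80_20 <- function(n, seed = 20240625L, val_fraction = 0.2) {
  check_scalar_number(n, "n", lower = 5)
  idx <- with_seed_ls(seed, sample.int(n))
  n_val <- round(val_fraction * n)
  list(train = sort(idx[-seq_len(n_val)]), val = sort(idx[seq_len(n_val)]))
}

#' Seeded k-fold assignment
#'
#' Random partition of `n` samples into `k` mutually exclusive folds of
#' near-equal size (exactly equal when `k` divides `n`).
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 5L, seed = 20240625L) {
  if (n < k) {
    abort_leafspad("Need at least as many samples as folds.",
                   "leafspad_parameter_error")
  }
  with_seed_ls(seed, sample(rep_len(seq_len(k), n)))
}

#' Model specifications for the five-model comparison
#'
#' Returns the default specification list naming the five models of the
#' comparison -- SVR, RVM, CNN, CNN-SVR, CNN-RVM -- with the study's
#' hyperparameters. Each element is a list with a `fit(X, y, seed)` closure
#' returning a fitted object usable with `predict`.
#'
#' @param svr An [svr_config()] shared by SVR and CNN-SVR.
#' @param rvm_gamma Gaussian-kernel width for the standalone RVM (0.01).
#' @param hybrid_rvm_gamma Gaussian-kernel width for CNN-RVM (0.05).
#' @param cnn_cfg A [cnn_train_config()].
#' @param models Character subset of
#'   `c("svr", "rvm", "cnn", "cnn_svr", "cnn_rvm")`.
#' @return Named list of model specs.
#' @export
spad_model_specs <- function(svr = svr_config(),
                             rvm_gamma = 0.01,
                             hybrid_rvm_gamma = 0.05,
                             cnn_cfg = cnn_train_config(),
                             models = c("svr", "rvm", "cnn", "cnn_svr",
                                        "cnn_rvm")) {
  models <- match.arg(models, several.ok = TRUE)
  all <- list(
    svr = list(fit = function(X, y, seed) fit_svr(X, y, config = svr)),
    rvm = list(fit = function(X, y, seed)
      fit_rvm(X, y, kernel = "gaussian", gamma = rvm_gamma)),
    cnn = list(fit = function(X, y, seed) {
      cfg <- cnn_cfg; cfg$seed <- seed
      train_cnn(X, y, arch = cnn_architecture(input_length = ncol(X)),
                cfg = cfg)
    }),
    cnn_svr = list(fit = function(X, y, seed) {
      cfg <- cnn_cfg; cfg$seed <- seed
      fit_hybrid(X, y, downstream = "svr",
                 arch = cnn_architecture_hybrid(input_length = ncol(X)),
                 cfg = cfg, svr = svr)
    }),
    cnn_rvm = list(fit = function(X, y, seed) {
      cfg <- cnn_cfg; cfg$seed <- seed
      fit_hybrid(X, y, downstream = "rvm",
                 arch = cnn_architecture_hybrid(input_length = ncol(X)),
                 cfg = cfg, rvm_gamma = hybrid_rvm_gamma)
    })
  )
  all[models]
}

# Fit selection + PCA on training rows of a feature table, project both
# partitions, returning score matrices and the preprocessing models.
preprocess_features <- function(table, train_idx, eval_idx,
                                selection_mode = "panel", threshold = 0.7,
                                n_components = 5L) {
  train_tbl <- table[train_idx, , drop = FALSE]
  report <- correlate_features(train_tbl)
  feats <- select_features(report, mode = selection_mode,
                           threshold = threshold)
  if (length(feats) == 0L) {
    abort_leafspad("Feature selection returned an empty set.",
                   "leafspad_config_error")
  }
  pca <- fit_pca(as.matrix(train_tbl[, feats, drop = FALSE]),
                 n_components = min(n_components, length(feats)))
  list(
    report = report, features = feats, pca = pca,
    X_train = stats::predict(pca,
                             as.matrix(table[train_idx, feats, drop = FALSE])),
    X_eval = stats::predict(pca,
                            as.matrix(table[eval_idx, feats, drop = FALSE]))
  )
}

#' Evaluate models on a seeded 80/20 split
#'
#' Splits the feature table 80/20, fits selection and PCA on the training
#' portion only (no leakage), trains every model spec on the training
#' scores, and reports train/validation RMSE and R-squared.
#'
#' @param table A [feature_table()].
#' @param models A [spad_model_specs()] list.
#' @param seed Integer seed driving the split and model training.
#' @param selection_mode,threshold Passed to [select_features()].
#' @param n_components Number of principal components (default 5).
#' @return Object of class `split_report`: tibble with one row per model
#'   and split, plus attributes `split` and `fits`.
#' @export
evaluate_split <- function(table, models = spad_model_specs(),
                           seed = 20240625L,
                           selection_mode = "panel", threshold = 0.7,
                           n_components = 5L) {
  sp <- split_80_20(nrow(table), seed = seed)
  prep <- preprocess_features(table, sp$train, sp$val,
                              selection_mode, threshold, n_components)
  y_tr <- table$spad[sp$train]; y_va <- table$spad[sp$val]
  fits <- list()
  rows <- purrr::imap_dfr(models, function(spec, name) {
    fit <- spec$fit(prep$X_train, y_tr, seed)
    fits[[name]] <<- fit
    pr_tr <- as_pred(stats::predict(fit, prep$X_train))
    pr_va <- as_pred(stats::predict(fit, prep$X_eval))
    tibble::tibble(
      model = name,
      split = c("train", "validation"),
      rmse = c(rmse(y_tr, pr_tr), rmse(y_va, pr_va)),
      r_squared = c(r_squared(y_tr, pr_tr), r_squared(y_va, pr_va))
    )
  })
  structure(rows, class = c("split_report", class(rows)),
            split = sp, fits = fits, preprocess = prep, seed = seed)
}

as_pred <- function(p) if (is.data.frame(p)) p$mean else p

#' k-fold cross-validation of the model comparison
#'
#' Partitions the samples into `k` mutually exclusive folds shared by all
#' models. In each iteration the remaining `k - 1` folds train the models
#' and the held-out fold validates them; by default feature selection and
#' PCA are refit on the training folds of each iteration so no information
#' leaks from the validation fold. `preprocess = "global"` instead fits
#' selection/PCA once on all samples before splitting, reproducing the
#' classical (leaky) protocol for comparison. Means and standard deviations
#' of RMSE and R-squared are aggregated over folds.
#'
#' @param table A [feature_table()].
#' @param models A [spad_model_specs()] list.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (folds and model training).
#' @param preprocess `"per_fold"` (default) or `"global"`.
#' @param selection_mode,threshold,n_components As in [evaluate_split()].
#' @return Object of class `cv_report`: list with `results` (per model x
#'   fold x split tibble), `summary` (means and SDs over folds), `folds`,
#'   `k`, `seed`.
#' @export
cross_validate <- function(table, models = spad_model_specs(), k = 5L,
                           seed = 20240625L,
                           preprocess = c("per_fold", "global"),
                           selection_mode = "panel", threshold = 0.7,
                           n_components = 5L) {
  preprocess <- match.arg(preprocess)
  n <- nrow(table)
  folds <- make_folds(n, k = k, seed = seed)
  global_prep <- NULL
  if (preprocess == "global") {
    global_prep <- preprocess_features(table, seq_len(n), seq_len(n),
                                       selection_mode, threshold,
                                       n_components)
  }
  results <- purrr::map_dfr(seq_len(k), function(fold) {
    va <- which(folds == fold); tr <- which(folds != fold)
    if (stats::sd(table$spad[va]) == 0 || stats::sd(table$spad[tr]) == 0) {
      abort_leafspad(sprintf("Fold %d has constant SPAD values.", fold),
                     "leafspad_fold_degenerate")
    }
    if (preprocess == "per_fold") {
      prep <- preprocess_features(table, tr, va, selection_mode,
                                  threshold, n_components)
      X_tr <- prep$X_train; X_va <- prep$X_eval
    } else {
      scores <- global_prep$X_train
      X_tr <- scores[tr, , drop = FALSE]; X_va <- scores[va, , drop = FALSE]
    }
    y_tr <- table$spad[tr]; y_va <- table$spad[va]
    purrr::imap_dfr(models, function(spec, name) {
      fit <- spec$fit(X_tr, y_tr, seed + fold)
      pr_tr <- as_pred(stats::predict(fit, X_tr))
      pr_va <- as_pred(stats::predict(fit, X_va))
      tibble::tibble(
        model = name, fold = fold,
        split = c("train", "validation"),
        rmse = c(rmse(y_tr, pr_tr), rmse(y_va, pr_va)),
        r_squared = c(r_squared(y_tr, pr_tr), r_squared(y_va, pr_va))
      )
    })
  })
  summary <- results |>
    dplyr::group_by(.data$model, .data$split) |>
    dplyr::summarise(
      mean_r_squared = mean(.data$r_squared),
      sd_r_squared = stats::sd(.data$r_squared),
      mean_rmse = mean(.data$rmse),
      sd_rmse = stats::sd(.data$rmse),
      .groups = "drop"
    )
  structure(list(results = results, summary = summary, folds = folds,
                 k = as.integer(k), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation, seed %d\n", x$k,
              x$seed))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$results

#' @export
glance.cv_report <- function(x, ...) x$summary

#' Model-comparison table in the standard layout
#'
#' One row per model: train/validation R-squared and RMSE with their
#' over-fold standard deviations. R-squared is given in percent.
#'
#' @param report A `cv_report`.
#' @return A tibble.
#' @export
comparison_table <- function(report) {
  s <- report$summary |>
    dplyr::mutate(split = ifelse(.data$split == "train", "train", "val"))
  wide <- tidyr::pivot_wider(
    s, names_from = "split",
    values_from = c("mean_r_squared", "sd_r_squared", "mean_rmse",
                    "sd_rmse"))
  tibble::tibble(
    model = wide$model,
    train_r2_pct = 100 * wide$mean_r_squared_train,
    train_r2_sd_pct = 100 * wide$sd_r_squared_train,
    train_rmse = wide$mean_rmse_train,
    train_rmse_sd = wide$sd_rmse_train,
    val_r2_pct = 100 * wide$mean_r_squared_val,
    val_r2_sd_pct = 100 * wide$sd_r_squared_val,
    val_rmse = wide$mean_rmse_val,
    val_rmse_sd = wide$sd_rmse_val
  )
}

#' Write a cross-validation report as CSV and Markdown
#'
#' @param report A `cv_report`.
#' @param path_csv,path_md Output paths (either may be `NULL`).
#' @export
write_cv_report <- function(report, path_csv = NULL, path_md = NULL) {
  tab <- comparison_table(report)
  if (!is.null(path_csv)) readr::write_csv(tab, path_csv)
  if (!is.null(path_md)) {
    num <- vapply(tab[-1], function(x) sprintf("%.3f", x), character(nrow(tab)))
    lines <- c(
      paste0("| model | ", paste(names(tab)[-1], collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
      vapply(seq_len(nrow(tab)), function(i) {
        paste0("| ", tab$model[i], " | ",
               paste(num[i, ], collapse = " | "), " |")
      }, character(1))
    )
    writeLines(lines, path_md)
  }
  invisible(tab)
}

#' Bar chart of cross-validated model performance
#' @param object A `cv_report`.
#' @param metric `"r_squared"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, metric = c("r_squared", "rmse"),
                               ...) {
  metric <- match.arg(metric)
  mcol <- paste0("mean_", metric); scol <- paste0("sd_", metric)
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data[[mcol]],
                                   fill = .data$split)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                   ymax = .data[[mcol]] + .data[[scol]]),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}
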