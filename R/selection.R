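#' Pearson correlation coefficient
#'
#' Sample Pearson correlation of two equal-length vectors. Errors on vectors
#' shorter than 3 or with zero variance, where the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A number in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_leafspad("`x` and `y` must have equal length >= 3.",
                   "leafspad_parameter_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_leafspad("Correlation undefined for a constant vector.",
                   "leafspad_undefined_correlation")
  }
  stats::cor(x, y)
}

#' Correlate every color feature with SPAD
#'
#' Computes the Pearson correlation of each feature column against the
#' `spad` column. Rows holding flagged missing feature values are excluded
#' per feature (pairwise complete observations).
#'
#' @param table A [feature_table()].
#' @return Object of class `correlation_report`: tibble with columns
#'   `feature`, `r`, `n`.
#' @export
correlate_features <- function(table) {
  feats <- intersect(color_feature_names(), names(table))
  if (!"spad" %in% names(table) || length(feats) == 0L) {
    abort_leafspad("`table` must carry a `spad` column and feature columns.",
                   "leafspad_schema_error")
  }
  rep <- purrr::map_dfr(feats, function(f) {
    ok <- stats::complete.cases(table[[f]], table$spad)
    tibble::tibble(feature = f,
                   r = pearson_r(table[[f]][ok], table$spad[ok]),
                   n = sum(ok))
  })
  structure(rep, class = c("correlation_report", class(rep)))
}

#' The default 21-feature panel
#'
#' The curated panel of 21 color indices strongly correlated with SPAD in
#' jujube leaves, in its canonical printed order. Note the panel is
#' list-based rather than a uniform cutoff: it includes `r-b` and `g-b`
#' while `r-g` (weakly correlated) is left out.
#'
#' @return Character vector of 21 feature names.
#' @export
spad_feature_panel <- function() {
  c("R", "G", "r", "g", "b", "r-b", "g-b", "R-B", "G-B", "R/B", "G/B",
    "(G+B-R)/(2R)", "(G+B-R)/(2G)",
    "(R-G-B)/(R+B)", "(R-G-B)/(R+G)", "(R-G-B)/(G+B)",
    "(B-G-R)/(R+B)", "(B-G-R)/(B+G)", "(B-G-R)/(G+R)",
    "(2G-R-B)/(2G+R+B)", "(G-B)/(G+B)")
}

#' Select features for modeling
#'
#' In `"panel"` mode (the default) returns the fixed 21-feature panel of
#' [spad_feature_panel()] in its printed order, erroring if any member is
#' absent from the report. In `"threshold"` mode returns all features with
#' `|r| >=` the threshold, ordered by `|r|` descending (ties by panel
#' order), which is the mode to use on new crops or acquisition setups.
#'
#' @param report A [correlate_features()] result.
#' @param mode `"panel"` or `"threshold"`.
#' @param threshold Absolute-correlation cutoff for threshold mode
#'   (default 0.7).
#' @return Character vector of selected feature names (possibly empty in
#'   threshold mode).
#' @export
select_features <- function(report, mode = c("panel", "threshold"),
                            threshold = 0.7) {
  mode <- match.arg(mode)
  if (mode == "panel") {
    panel <- spad_feature_panel()
    missing <- setdiff(panel, report$feature)
    if (length(missing)) {
      abort_leafspad(paste0("Panel features absent from the report: ",
                            paste(missing, collapse = ", ")),
                     "leafspad_config_error")
    }
    return(panel)
  }
  check_scalar_number(threshold, "threshold", lower = 0)
  keep <- report[abs(report$r) >= threshold, , drop = FALSE]
  keep$feature[order(-abs(keep$r), match(keep$feature, report$feature))]
}

#' Write a correlation report as CSV
#' @param report A [correlate_features()] result.
#' @param path CSV path.
#' @export
write_correlation_report <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}

#' Lollipop chart of feature--SPAD correlations
#'
#' @param object A `correlation_report`.
#' @param threshold Reference lines drawn at `±threshold`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_report <- function(object, threshold = 0.7, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$r)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$feature)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$r,
                                       yend = .data$feature),
                          color = "grey60") +
    ggplot2::geom_point(size = 2, color = "forestgreen") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "Pearson r with SPAD", y = NULL) +
    ggplot2::theme_minimal()
}
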