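#' Names of the 28 color features
#'
#' The panel comprises 22 RGB-derived indices (channels, differences, ratios
#' and compound algebraic indices) and 6 normalized-rgb features, where
#' `r = R/(R+G+B)` etc. Names are compact ASCII renderings of the algebra
#' (e.g. `"(G+B-R)/(2G)"`) and are used verbatim as column names in every
#' table and CSV the package writes.
#'
#' @return Character vector of length 28.
#' @export
color_feature_names <- function() {
  c("R", "G", "B",
    "R-G", "R-B", "G-B",
    "R/G", "R/B", "G/B",
    "(G-R)/(G+R)",
    "(G+B-R)/(2R)", "(G+B-R)/(2G)", "(G+B-R)/(2B)",
    "(R-G-B)/(R+B)", "(R-G-B)/(R+G)", "(R-G-B)/(G+B)",
    "(B-G-R)/(R+B)", "(B-G-R)/(B+G)", "(B-G-R)/(G+R)",
    "(2G-R-B)/(2G+R+B)",
    "(G-B)/(G+B)", "(G-B)B/(R+G)",
    "r", "g", "b",
    "r-g", "r-b", "g-b")
}

# safe division: zero denominators become NA (flagged, never silently zero)
div0 <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Compute the 28 color features from mean channel colors
#'
#' Evaluates every index of the panel on the mean red/green/blue intensities
#' of one or more leaves. Ratio-form features with a zero denominator are
#' returned as `NA` with a warning and should be excluded from downstream
#' correlation and PCA fitting; for real leaf colors this cannot occur.
#'
#' @param colors Data frame with columns `mean_R`, `mean_G`, `mean_B`
#'   (one row per leaf), as produced by [mean_channels()].
#' @return Tibble with one row per input row and 28 named columns.
#' @export
#' @examples
#' compute_color_features(tibble::tibble(mean_R = 100, mean_G = 150,
#'                                       mean_B = 50))
compute_color_features <- function(colors) {
  colors <- tibble::as_tibble(colors)
  need <- c("mean_R", "mean_G", "mean_B")
  if (!all(need %in% names(colors))) {
    abort_leafspad("`colors` must have columns mean_R, mean_G, mean_B.",
                   "leafspad_parameter_error")
  }
  R <- colors$mean_R; G <- colors$mean_G; B <- colors$mean_B
  if (length(R) && (any(c(R, G, B) < 0) || any(c(R, G, B) > 255))) {
    abort_leafspad("Mean channel values must lie in [0, 255].",
                   "leafspad_parameter_error")
  }
  tot <- R + G + B
  r <- div0(R, tot); g <- div0(G, tot); b <- div0(B, tot)
  out <- tibble::tibble(
    R, G, B,
    `R-G` = R - G, `R-B` = R - B, `G-B` = G - B,
    `R/G` = div0(R, G), `R/B` = div0(R, B), `G/B` = div0(G, B),
    `(G-R)/(G+R)` = div0(G - R, G + R),
    `(G+B-R)/(2R)` = div0(G + B - R, 2 * R),
    `(G+B-R)/(2G)` = div0(G + B - R, 2 * G),
    `(G+B-R)/(2B)` = div0(G + B - R, 2 * B),
    `(R-G-B)/(R+B)` = div0(R - G - B, R + B),
    `(R-G-B)/(R+G)` = div0(R - G - B, R + G),
    `(R-G-B)/(G+B)` = div0(R - G - B, G + B),
    `(B-G-R)/(R+B)` = div0(B - G - R, R + B),
    `(B-G-R)/(B+G)` = div0(B - G - R, B + G),
    `(B-G-R)/(G+R)` = div0(B - G - R, G + R),
    `(2G-R-B)/(2G+R+B)` = div0(2 * G - R - B, 2 * G + R + B),
    `(G-B)/(G+B)` = div0(G - B, G + B),
    `(G-B)B/(R+G)` = div0((G - B) * B, R + G),
    r = r, g = g, b = b,
    `r-g` = r - g, `r-b` = r - b, `g-b` = g - b
  )
  if (anyNA(out)) {
    rlang::warn(
      "Zero denominators produced flagged missing feature values.",
      class = "leafspad_zero_denominator")
  }
  out
}

#' Assemble a feature table aligned with SPAD values
#'
#' @param colors Data frame of mean channel colors (see
#'   [compute_color_features()]); an optional `filename` column is checked
#'   for duplicates.
#' @param spad Numeric vector of measured SPAD values, one per row of
#'   `colors`.
#' @return Tibble with a `spad` column followed by the 28 feature columns.
#' @export
feature_table <- function(colors, spad) {
  colors <- tibble::as_tibble(colors)
  if (nrow(colors) != length(spad)) {
    abort_leafspad(sprintf(
      "%d color rows but %d SPAD values; inputs must align.",
      nrow(colors), length(spad)), "leafspad_alignment_error")
  }
  if ("filename" %in% names(colors)) {
    dup <- unique(colors$filename[duplicated(colors$filename)])
    if (length(dup)) {
      abort_leafspad(paste0("Duplicate filenames in manifest: ",
                            paste(dup, collapse = ", ")),
                     "leafspad_alignment_error")
    }
  }
  if (nrow(colors) == 0L) {
    feats <- compute_color_features(
      tibble::tibble(mean_R = numeric(), mean_G = numeric(),
                     mean_B = numeric()))
    return(dplyr::bind_cols(tibble::tibble(spad = numeric()), feats))
  }
  dplyr::bind_cols(tibble::tibble(spad = as.numeric(spad)),
                   compute_color_features(colors))
}

#' Write / read a feature table as CSV
#'
#' The CSV carries the `spad` column plus the 28 feature columns under their
#' exact names; `read_feature_table()` validates the schema on the way in so
#' the round trip is loss-free.
#'
#' @param table A feature table from [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("spad", color_feature_names()), names(tbl))
  if (length(missing)) {
    abort_leafspad(paste0("Feature CSV lacks columns: ",
                          paste(missing, collapse = ", ")),
                   "leafspad_schema_error")
  }
  tibble::as_tibble(tbl)
}
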