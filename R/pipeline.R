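#' Pipeline configuration
#'
#' Resolved configuration for an end-to-end run: input locations, the
#' segmentation thresholds, feature-selection mode, PCA dimension, which
#' models to fit, and the evaluation protocol. Unknown keys are rejected so
#' typos fail loudly; every run writes the fully resolved configuration
#' alongside its outputs.
#'
#' @param images_dir Directory of leaf photographs.
#' @param manifest CSV path with columns `filename, spad`.
#' @param out_dir Output directory.
#' @param segmentation A [segmentation_config()].
#' @param selection_mode,threshold Passed to [select_features()].
#' @param n_components Principal components kept (default 5).
#' @param models Character subset of the five model names.
#' @param svr An [svr_config()].
#' @param rvm_gamma,hybrid_rvm_gamma Standalone / hybrid RVM kernel widths.
#' @param cnn A [cnn_train_config()].
#' @param seed Master seed for split, folds, and training.
#' @param cross_validation Run 5-fold cross-validation as well?
#' @param preprocess `"per_fold"` or `"global"` (see [cross_validate()]).
#' @param ... Rejected; any unknown key is an error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(images_dir = NULL, manifest = NULL,
                            out_dir = NULL,
                            segmentation = segmentation_config(),
                            selection_mode = "panel", threshold = 0.7,
                            n_components = 5L,
                            models = c("svr", "rvm", "cnn", "cnn_svr",
                                       "cnn_rvm"),
                            svr = svr_config(),
                            rvm_gamma = 0.01, hybrid_rvm_gamma = 0.05,
                            cnn = cnn_train_config(),
                            seed = 20240625L,
                            cross_validation = FALSE,
                            preprocess = "per_fold", ...) {
  extra <- list(...)
  if (length(extra)) {
    abort_leafspad(paste0("Unknown configuration key(s): ",
                          paste(names(extra), collapse = ", ")),
                   "leafspad_config_error")
  }
  structure(list(images_dir = images_dir, manifest = manifest,
                 out_dir = out_dir, segmentation = segmentation,
                 selection_mode = selection_mode, threshold = threshold,
                 n_components = as.integer(n_components), models = models,
                 svr = svr, rvm_gamma = rvm_gamma,
                 hybrid_rvm_gamma = hybrid_rvm_gamma, cnn = cnn,
                 seed = as.integer(seed),
                 cross_validation = isTRUE(cross_validation),
                 preprocess = preprocess),
            class = "pipeline_config")
}

#' Extract mean leaf colors from a set of images
#'
#' Segments each image, median-filters the region of interest, and computes
#' the mean channel color. Errors are rethrown naming the offending sample.
#'
#' @param images List of `H x W x 3` arrays, or character vector of file
#'   paths.
#' @param cfg A [segmentation_config()].
#' @param names Optional sample names for error reporting.
#' @return Tibble with `filename` (when names are given), `mean_R`,
#'   `mean_G`, `mean_B`, `n_pixels`; masks are attached as the `"masks"`
#'   attribute.
#' @export
extract_leaf_colors <- function(images, cfg = segmentation_config(),
                                names = NULL) {
  paths <- NULL
  if (is.character(images)) {
    paths <- images
    if (is.null(names)) names <- basename(paths)
    images <- lapply(paths, load_image)
  }
  masks <- vector("list", length(images))
  rows <- purrr::map_dfr(seq_along(images), function(i) {
    id <- if (!is.null(names)) names[i] else as.character(i)
    tryCatch({
      img <- images[[i]]
      mask <- segment_leaf(img, cfg)
      masks[[i]] <<- mask
      filtered <- median_filter_roi(img, mask, kernel = cfg$kernel)
      mean_channels(filtered, mask)
    }, leafspad_error = function(e) {
      abort_leafspad(sprintf("Stage 'segment/features' failed on %s: %s",
                             id, conditionMessage(e)),
                     class(e)[1], parent = e)
    })
  })
  if (!is.null(names)) {
    rows <- dplyr::bind_cols(tibble::tibble(filename = names), rows)
  }
  attr(rows, "masks") <- masks
  rows
}

#' Fit the full SPAD pipeline in memory
#'
#' Runs segment -> color features -> correlation selection -> PCA ->
#' model fitting -> 80/20 evaluation on an in-memory dataset (images plus
#' SPAD values), and returns a deployable pipeline object that carries the
#' segmentation config, the fitted selection and PCA, and the fitted
#' models.
#'
#' @param images List of `H x W x 3` arrays or character vector of paths.
#' @param spad Numeric SPAD vector aligned with `images`.
#' @param config A [pipeline_config()].
#' @return Object of class `spad_pipeline`: list with `colors`, `table`,
#'   `report` (a [evaluate_split()] result), `correlations`, `features`,
#'   `pca`, `models`, `config`, and optionally `cv` (a [cross_validate()]
#'   result).
#' @export
fit_spad_pipeline <- function(images, spad, config = pipeline_config()) {
  colors <- extract_leaf_colors(images, config$segmentation)
  table <- feature_table(colors, spad)
  specs <- spad_model_specs(svr = config$svr,
                            rvm_gamma = config$rvm_gamma,
                            hybrid_rvm_gamma = config$hybrid_rvm_gamma,
                            cnn_cfg = config$cnn,
                            models = config$models)
  report <- evaluate_split(table, specs, seed = config$seed,
                           selection_mode = config$selection_mode,
                           threshold = config$threshold,
                           n_components = config$n_components)
  prep <- attr(report, "preprocess")
  cv <- NULL
  if (config$cross_validation) {
    cv <- cross_validate(table, specs, k = 5L, seed = config$seed,
                         preprocess = config$preprocess,
                         selection_mode = config$selection_mode,
                         threshold = config$threshold,
                         n_components = config$n_components)
  }
  structure(list(
    colors = colors, table = table, report = report, cv = cv,
    correlations = prep$report, features = prep$features, pca = prep$pca,
    models = attr(report, "fits"), config = config
  ), class = "spad_pipeline")
}

#' @export
print.spad_pipeline <- function(x, ...) {
  cat(sprintf("<spad_pipeline> %d samples, %d features -> %d components\n",
              nrow(x$table), length(x$features), x$pca$k))
  print(tibble::as_tibble(x$report))
  invisible(x)
}

#' Run the configured pipeline over a directory of images
#'
#' Reads the manifest, loads and processes every image, fits and evaluates
#' the configured models, and writes all artifacts to `out_dir`: the
#' feature CSV, correlation report, PCA model (JSON), leaf masks (PNG), the
#' model-comparison report (CSV and Markdown when cross-validating), the
#' resolved configuration and a provenance record (JSON). Given identical
#' inputs, configuration and seed, every output is byte-identical across
#' runs.
#'
#' @param config A [pipeline_config()] with `images_dir`, `manifest` and
#'   `out_dir` set.
#' @return The fitted `spad_pipeline`, invisibly.
#' @export
run_pipeline <- function(config) {
  for (key in c("images_dir", "manifest", "out_dir")) {
    if (is.null(config[[key]])) {
      abort_leafspad(sprintf("`%s` must be set to run the pipeline.", key),
                     "leafspad_config_error")
    }
  }
  manifest <- readr::read_csv(config$manifest, show_col_types = FALSE)
  if (!all(c("filename", "spad") %in% names(manifest))) {
    abort_leafspad("Manifest must have columns `filename` and `spad`.",
                   "leafspad_schema_error")
  }
  paths <- file.path(config$images_dir, manifest$filename)
  missing <- manifest$filename[!file.exists(paths)]
  if (length(missing)) {
    abort_leafspad(paste0("Stage 'ingest': missing image file(s): ",
                          paste(missing, collapse = ", ")),
                   "leafspad_io_error")
  }
  dup <- unique(manifest$filename[duplicated(manifest$filename)])
  if (length(dup)) {
    abort_leafspad(paste0("Duplicate filenames in manifest: ",
                          paste(dup, collapse = ", ")),
                   "leafspad_alignment_error")
  }
  pipe <- fit_spad_pipeline(stats::setNames(paths, manifest$filename),
                            manifest$spad, config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(pipe$table, file.path(out, "features.csv"))
  write_correlation_report(pipe$correlations,
                           file.path(out, "correlations.csv"))
  write_pca(pipe$pca, file.path(out, "pca.json"))
  mask_dir <- file.path(out, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  masks <- attr(pipe$colors, "masks")
  for (i in seq_along(masks)) {
    write_mask_png(masks[[i]], file.path(mask_dir, paste0(
      tools::file_path_sans_ext(manifest$filename[i]), "_mask.png")))
  }
  readr::write_csv(tibble::as_tibble(pipe$report),
                   file.path(out, "split_report.csv"))
  if (!is.null(pipe$cv)) {
    write_cv_report(pipe$cv, file.path(out, "cv_report.csv"),
                    file.path(out, "cv_report.md"))
  }
  resolved <- resolve_config(config)
  jsonlite::write_json(resolved, file.path(out, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  provenance <- list(
    package = "leafspad",
    version = as.character(utils::packageVersion("leafspad")),
    seed = config$seed,
    n_samples = nrow(manifest),
    config_hash = rlang::hash(resolved)
  )
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(pipe)
}

resolve_config <- function(config) {
  x <- unclass(config)
  lapply(x, function(el) {
    if (is.list(el) || inherits(el, "segmentation_config")) {
      resolve_config(el)
    } else {
      el
    }
  })
}

#' Predict the SPAD value of a single leaf photograph
#'
#' Segments the leaf, extracts the color features used at training time,
#' projects them through the stored PCA, and applies a fitted model.
#' Deterministic; a segmentation failure surfaces as a `NoLeafFound`-style
#' error with a remediation hint.
#'
#' @param pipeline A fitted `spad_pipeline`.
#' @param image An `H x W x 3` array or a file path.
#' @param model Model name among the fitted ones (default `"cnn_svr"` if
#'   present, else the first).
#' @return A single predicted SPAD value.
#' @export
predict_single <- function(pipeline, image,
                           model = NULL) {
  if (is.character(image)) image <- load_image(image)
  if (is.null(model)) {
    model <- if ("cnn_svr" %in% names(pipeline$models)) "cnn_svr" else
      names(pipeline$models)[1]
  }
  if (!model %in% names(pipeline$models)) {
    abort_leafspad(sprintf("Model '%s' was not fitted in this pipeline.",
                           model), "leafspad_config_error")
  }
  mask <- tryCatch(
    segment_leaf(image, pipeline$config$segmentation),
    leafspad_no_leaf = function(e) {
      abort_leafspad(paste0(
        conditionMessage(e),
        " Hint: check that the leaf is darker/more saturated than the",
        " background, or relax `s_min`/`v_max` in segmentation_config()."),
        "leafspad_no_leaf")
    })
  filtered <- median_filter_roi(image, mask,
                                kernel = pipeline$config$segmentation$kernel)
  colors <- mean_channels(filtered, mask)
  feats <- compute_color_features(colors)
  scores <- stats::predict(pipeline$pca,
                           as.matrix(feats[, pipeline$features,
                                           drop = FALSE]))
  as_pred(stats::predict(pipeline$models[[model]], scores))
}
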