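#' Configuration for the synthetic leaf-image generator
#'
#' The generator emulates the acquisition conditions of a light-box leaf
#' photograph: a single leaf (an ellipse with random eccentricity and
#' rotation, optionally carrying a darker midrib stripe) on a near-white
#' background under even illumination. Chlorophyll readings (SPAD units) are
#' drawn from a truncated normal matching the field campaign this package
#' models (520 jujube leaves: mean 42.05, SD 5.99, range 21.90--55.90), and
#' the mean leaf color responds linearly and monotonically to the
#' standardized SPAD value: greener and bluer, less red-dominant, as
#' chlorophyll rises.
#'
#' With standardized SPAD \eqn{\tilde s}, the noise-free leaf color is
#' \deqn{(R, G, B) = (R_0 - a_R \tilde s,\; G_0 + a_G \tilde s,\; B_0 + a_B \tilde s)}
#' so that red-dominance indices such as \eqn{R-B} fall with SPAD while
#' green/blue indices such as \eqn{(G+B-R)/2G} rise, reproducing the sign
#' structure observed on real leaves.
#'
#' @param n_samples Number of leaves in a generated dataset (default 520).
#' @param spad_mean,spad_sd Mean and SD of the underlying normal (42.05, 5.99).
#' @param spad_min,spad_max Truncation bounds (21.90, 55.90).
#' @param image_size Integer vector `c(height, width)` in pixels; 256 x 256 by
#'   default (full-resolution photographs are emulated by raising this).
#' @param base_rgb Noise-free leaf color at `spad == spad_mean` (default
#'   (90, 130, 60)).
#' @param response Positive coefficients `c(a_R, a_G, a_B)` of the linear
#'   color response (default (25, 10, 8)); `a_R` is subtracted, the others
#'   added.
#' @param noise_sd Per-pixel Gaussian channel noise SD in intensity units
#'   (default 4).
#' @param illumination_gradient Relative amplitude of a horizontal shading
#'   ramp across the image (default 0 = even illumination).
#' @param background_rgb Background color (default (250, 250, 250)).
#' @param background_jitter Half-range of the uniform per-image background
#'   color jitter (default 3).
#' @param midrib Draw a darker midrib stripe along the major axis
#'   (default `FALSE`, so the default noiseless leaf is perfectly uniform).
#' @param seed Integer seed governing every random draw of the generator.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @seealso [sample_spad()], [render_leaf()], [generate_leaf_dataset()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_samples = 10, image_size = c(64, 64))
#' spad <- sample_spad(cfg, 10)
#' leaf <- render_leaf(spad[1], cfg, seed = 1)
#' dim(leaf$image)
synthetic_config <- function(n_samples = 520L,
                             spad_mean = 42.05, spad_sd = 5.99,
                             spad_min = 21.90, spad_max = 55.90,
                             image_size = c(256L, 256L),
                             base_rgb = c(90, 130, 60),
                             response = c(25, 10, 8),
                             noise_sd = 4,
                             illumination_gradient = 0,
                             background_rgb = c(250, 250, 250),
                             background_jitter = 3,
                             midrib = FALSE,
                             seed = 20240625L) {
  check_scalar_number(n_samples, "n_samples", lower = 1)
  check_scalar_number(spad_sd, "spad_sd", lower = 1e-12)
  if (spad_min > spad_max) {
    abort_leafspad("SPAD truncation bounds are inverted.",
                   "leafspad_config_error")
  }
  if (length(image_size) != 2L || any(image_size < 8)) {
    abort_leafspad("`image_size` must be c(height, width), each >= 8 px.",
                   "leafspad_config_error")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  cfg <- list(
    n_samples = as.integer(n_samples),
    spad_mean = spad_mean, spad_sd = spad_sd,
    spad_min = spad_min, spad_max = spad_max,
    image_size = as.integer(image_size),
    base_rgb = base_rgb, response = response,
    noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    background_rgb = background_rgb,
    background_jitter = background_jitter,
    midrib = isTRUE(midrib),
    seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

#' Draw SPAD values from the generator's truncated normal
#'
#' Inverse-CDF sampling of a normal truncated to
#' `[cfg$spad_min, cfg$spad_max]`; exact (no rejection) and reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param n Number of draws.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return Numeric vector of length `n`, all values within the bounds.
#' @export
sample_spad <- function(cfg, n, seed = cfg$seed) {
  check_scalar_number(n, "n", lower = 1)
  if (cfg$spad_min > cfg$spad_max) {
    abort_leafspad("SPAD truncation bounds are inverted.",
                   "leafspad_config_error")
  }
  if (cfg$spad_min == cfg$spad_max) {
    return(rep(cfg$spad_min, n))
  }
  lo <- stats::pnorm(cfg$spad_min, cfg$spad_mean, cfg$spad_sd)
  hi <- stats::pnorm(cfg$spad_max, cfg$spad_mean, cfg$spad_sd)
  u <- with_seed_ls(seed, stats::runif(n, lo, hi))
  out <- stats::qnorm(u, cfg$spad_mean, cfg$spad_sd)
  pmin(pmax(out, cfg$spad_min), cfg$spad_max)
}

# Noise-free leaf color for a SPAD value under the linear response.
leaf_color_for_spad <- function(spad, cfg) {
  s <- (spad - cfg$spad_mean) / cfg$spad_sd
  rgb <- c(cfg$base_rgb[1] - cfg$response[1] * s,
           cfg$base_rgb[2] + cfg$response[2] * s,
           cfg$base_rgb[3] + cfg$response[3] * s)
  if (any(rgb <= 0) || any(rgb >= 255)) {
    abort_leafspad(
      "Color response pushes the mean leaf color outside (0, 255).",
      "leafspad_config_error")
  }
  rgb
}

#' Render one synthetic leaf image with ground truth
#'
#' Draws an elliptical leaf with random eccentricity and rotation, colors it
#' with the noise-free SPAD-responsive mean color plus per-pixel Gaussian
#' noise, and composites it on a near-white background. The exact mask and
#' the noise-free mean color are returned as ground truth.
#'
#' @param spad SPAD value, within the config bounds.
#' @param cfg A [synthetic_config()].
#' @param seed Seed for this leaf's geometry and noise.
#' @return List with `image` (H x W x 3 array, 0--255 integers), `mask`
#'   (H x W 0/1 matrix), and `mean_rgb` (noise-free leaf color).
#' @export
render_leaf <- function(spad, cfg, seed = cfg$seed) {
  if (spad < cfg$spad_min - 1e-9 || spad > cfg$spad_max + 1e-9) {
    abort_leafspad("`spad` is outside the configured bounds.",
                   "leafspad_config_error")
  }
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  leaf_rgb <- leaf_color_for_spad(spad, cfg)

  with_seed_ls(seed, {
    # ellipse geometry: centered with jitter, random axes and rotation
    cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
    a  <- stats::runif(1, 0.28, 0.40) * min(h, w)      # semi-major
    b  <- a * stats::runif(1, 0.45, 0.85)              # semi-minor
    th <- stats::runif(1, 0, pi)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    u <-  (cols - cx) * cos(th) + (rows - cy) * sin(th)
    v <- -(cols - cx) * sin(th) + (rows - cy) * cos(th)
    mask <- ((u / a)^2 + (v / b)^2) <= 1
    if (!any(mask)) {
      abort_leafspad("Requested image size yields an empty leaf.",
                     "leafspad_config_error")
    }

    bg <- cfg$background_rgb +
      stats::runif(3, -cfg$background_jitter, cfg$background_jitter)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- bg[ch]

    leaf_px <- array(rep(leaf_rgb, each = sum(mask)), dim = c(sum(mask), 3))
    if (cfg$midrib) {
      on_rib <- abs(v[mask]) < pmax(1, 0.03 * b) & abs(u[mask]) < 0.9 * a
      leaf_px[on_rib, ] <- sweep(leaf_px[on_rib, , drop = FALSE], 2,
                                 c(0.85, 0.85, 0.85), `*`)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- leaf_px[, ch]
      img[, , ch] <- plane
    }
    if (cfg$noise_sd > 0) {
      img <- img + array(stats::rnorm(h * w * 3, 0, cfg$noise_sd),
                         dim = c(h, w, 3))
    }
    if (cfg$illumination_gradient != 0) {
      ramp <- 1 + cfg$illumination_gradient *
        (matrix(seq_len(w), h, w, byrow = TRUE) / w - 0.5)
      img <- img * array(rep(ramp, 3), dim = c(h, w, 3))
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, mask = matrix(as.integer(mask), h, w),
         mean_rgb = leaf_rgb)
  })
}

#' Generate a full synthetic leaf dataset
#'
#' Draws `cfg$n_samples` SPAD values, renders one leaf image per value, and
#' assembles a manifest. With `out_dir` given, images and ground-truth masks
#' are written as PNG and the manifest as CSV (`filename, spad, mean_R,
#' mean_G, mean_B, mask`); otherwise everything stays in memory. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `leaf_dataset`: list with `manifest` (tibble),
#'   `images` and `masks` (lists of arrays, kept in memory whether or not
#'   the dataset was also written to disk), and `config`.
#' @export
generate_leaf_dataset <- function(cfg, out_dir = NULL) {
  n <- cfg$n_samples
  spad <- sample_spad(cfg, n, seed = cfg$seed)
  # independent per-leaf seeds derived from the master seed
  leaf_seeds <- with_seed_ls(cfg$seed + 1L,
                             sample.int(.Machine$integer.max - 1L, n))
  leaves <- purrr::map2(spad, leaf_seeds, function(s, sd) {
    render_leaf(s, cfg, seed = sd)
  })
  fname <- sprintf("leaf_%04d.png", seq_len(n))
  manifest <- tibble::tibble(
    filename = fname,
    spad = spad,
    mean_R = purrr::map_dbl(leaves, ~ .x$mean_rgb[1]),
    mean_G = purrr::map_dbl(leaves, ~ .x$mean_rgb[2]),
    mean_B = purrr::map_dbl(leaves, ~ .x$mean_rgb[3]),
    mask = sprintf("mask_%04d.png", seq_len(n))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image_png(leaves[[i]]$image, file.path(out_dir, fname[i]))
      png::writePNG(leaves[[i]]$mask * 1.0,
                    file.path(out_dir, manifest$mask[i]))
    }
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  structure(list(
    manifest = manifest,
    images = purrr::map(leaves, "image"),
    masks = purrr::map(leaves, "mask"),
    config = cfg
  ), class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf("<leaf_dataset> %d synthetic leaves, %dx%d px, seed %d\n",
              nrow(x$manifest), x$config$image_size[1],
              x$config$image_size[2], x$config$seed))
  print(x$manifest, n = 5)
  invisible(x)
}
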