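#' Read a leaf photograph into an RGB array
#'
#' Decodes a JPEG or PNG file into an `H x W x 3` numeric array of 8-bit
#' intensities (0--255) in red, green, blue channel order, independent of the
#' on-disk channel layout. Grayscale images are replicated across channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a JPEG or PNG file.
#' @return `H x W x 3` numeric array with values in 0--255.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    abort_leafspad(sprintf("Image file not found: %s", path),
                   "leafspad_io_error")
  }
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  raw <- tryCatch({
    if (is_png) {
      png::readPNG(path)
    } else {
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores x (columns) first; transpose to rows x cols
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    }
  }, error = function(e) {
    abort_leafspad(sprintf("Cannot decode image %s: %s", path,
                           conditionMessage(e)), "leafspad_io_error")
  })
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  }
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L) {
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  }
  round(raw * 255)
}

# write an 0-255 H x W x 3 array as PNG
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion. Hue is returned in degrees `[0, 360)`,
#' saturation and value in `[0, 1]`. Achromatic pixels (including black)
#' have hue and saturation 0. Users of the 8-bit OpenCV convention (hue in
#' 0--179) should divide hue by 2 to compare.
#'
#' @param img `H x W x 3` array with values in 0--255.
#' @return `H x W x 3` array: hue (degrees), saturation, value.
#' @export
rgb_to_hsv <- function(img) {
  check_image(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  hsv[is.na(hsv)] <- 0
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

#' Segmentation configuration
#'
#' Thresholds for separating a leaf from a bright background in HSV space.
#' The white background is high-value and low-saturation, so pixels with
#' saturation at or above `s_min` and value at or below `v_max` are
#' foreground candidates. An optional hue gate restricts candidates to a hue
#' interval (degrees); `c(40, 180)` covers green foliage and is useful on
#' busier scenes, but is off by default.
#'
#' @param s_min Minimum saturation of foreground pixels (default 0.15).
#' @param v_max Maximum value of foreground pixels (default 0.98).
#' @param hue_range `NULL` (no hue gate) or `c(lo, hi)` in degrees.
#' @param kernel Median-filter kernel width (odd, default 5).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(s_min = 0.15, v_max = 0.98,
                                hue_range = NULL, kernel = 5L) {
  check_scalar_number(s_min, "s_min", 0, 1)
  check_scalar_number(v_max, "v_max", 0, 1)
  if (!is.null(hue_range) &&
      (length(hue_range) != 2L || hue_range[1] > hue_range[2])) {
    abort_leafspad("`hue_range` must be NULL or c(lo, hi) with lo <= hi.",
                   "leafspad_parameter_error")
  }
  check_kernel(kernel)
  structure(list(s_min = s_min, v_max = v_max, hue_range = hue_range,
                 kernel = as.integer(kernel)),
            class = "segmentation_config")
}

check_kernel <- function(kernel) {
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel < 1 ||
      kernel %% 2 != 1) {
    abort_leafspad("`kernel` must be a positive odd integer.",
                   "leafspad_parameter_error")
  }
  invisible(kernel)
}

#' Segment the leaf from a bright background
#'
#' Thresholds the HSV representation (foreground = saturated, not-too-bright
#' pixels, optionally hue-gated), labels connected components, keeps the
#' largest one, and fills holes inside its contour so the mask is the filled
#' region of interest. Ties on component area are broken by the smallest
#' top-left pixel in row-major order.
#'
#' @param img `H x W x 3` array, 0--255.
#' @param cfg A [segmentation_config()].
#' @return Object of class `leaf_mask`: list with `mask` (H x W 0/1 integer
#'   matrix), `contour` (n x 2 matrix of row/col boundary coordinates), and
#'   `area_px`.
#' @export
segment_leaf <- function(img, cfg = segmentation_config()) {
  check_image(img)
  hsv <- rgb_to_hsv(img)
  cand <- hsv[, , 2] >= cfg$s_min & hsv[, , 3] <= cfg$v_max
  if (!is.null(cfg$hue_range)) {
    cand <- cand & hsv[, , 1] >= cfg$hue_range[1] &
      hsv[, , 1] <= cfg$hue_range[2]
  }
  if (!any(cand)) {
    abort_leafspad("No foreground pixels after HSV thresholding.",
                   "leafspad_no_leaf")
  }
  labels <- EBImage::bwlabel(cand * 1L)
  areas <- tabulate(labels[labels > 0])
  biggest <- which(areas == max(areas))
  if (length(biggest) > 1L) {
    # deterministic tie-break: smallest top-left pixel in row-major order
    first_seen <- vapply(biggest, function(lab) {
      idx <- which(labels == lab)
      rc <- arrayInd(idx, dim(labels))
      min((rc[, 1] - 1) * ncol(labels) + rc[, 2])
    }, numeric(1))
    biggest <- biggest[which.min(first_seen)]
  }
  comp <- labels == biggest
  filled <- EBImage::fillHull(EBImage::Image(comp * 1)) > 0.5
  filled <- matrix(as.integer(filled), nrow(comp), ncol(comp))
  oc <- EBImage::ocontour(EBImage::Image(filled))[[1]]
  # ocontour returns 0-based (x, y) on the matrix as given: x indexes dim 1
  contour <- cbind(row = oc[, 1] + 1L, col = oc[, 2] + 1L)
  structure(list(mask = filled, contour = contour,
                 area_px = sum(filled)), class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d px over a %d x %d image\n",
              x$area_px, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Median-filter the region of interest
#'
#' Applies a per-channel square median filter of width `kernel`, replacing
#' only pixels inside the mask; everything outside is returned unchanged.
#' `kernel = 1` is the identity.
#'
#' @param img `H x W x 3` array, 0--255.
#' @param mask A [segment_leaf()] result (or an H x W 0/1 matrix).
#' @param kernel Odd positive filter width (default 5).
#' @return Filtered `H x W x 3` array.
#' @export
median_filter_roi <- function(img, mask, kernel = 5L) {
  check_image(img)
  check_kernel(kernel)
  m <- if (inherits(mask, "leaf_mask")) mask$mask else mask
  if (!all(dim(m) == dim(img)[1:2])) {
    abort_leafspad("Mask dimensions do not match the image.",
                   "leafspad_parameter_error")
  }
  if (kernel == 1L) return(img)
  radius <- (kernel - 1L) / 2L
  out <- img
  inside <- m == 1L
  for (ch in 1:3) {
    f <- EBImage::medianFilter(img[, , ch] / 255, radius) * 255
    plane <- out[, , ch]
    plane[inside] <- round(f[inside])
    out[, , ch] <- plane
  }
  out
}

#' Mean channel intensities over the leaf region
#'
#' Arithmetic mean of each RGB channel over masked pixels only, the single
#' color measurement from which all downstream indices are computed.
#'
#' @param img `H x W x 3` array, 0--255.
#' @param mask A [segment_leaf()] result (or an H x W 0/1 matrix).
#' @return One-row tibble with `mean_R`, `mean_G`, `mean_B`, `n_pixels`.
#' @export
mean_channels <- function(img, mask) {
  check_image(img)
  m <- if (inherits(mask, "leaf_mask")) mask$mask else mask
  inside <- m == 1L
  if (!any(inside)) {
    abort_leafspad("Empty region of interest.", "leafspad_empty_roi")
  }
  tibble::tibble(
    mean_R = mean(img[, , 1][inside]),
    mean_G = mean(img[, , 2][inside]),
    mean_B = mean(img[, , 3][inside]),
    n_pixels = sum(inside)
  )
}

#' Write a leaf mask as a single-channel PNG (0/255)
#' @param mask A [segment_leaf()] result or 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "leaf_mask")) mask$mask else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}
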