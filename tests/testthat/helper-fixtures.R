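# Programmatic fixtures and independent oracles shared across test files.

# uniform-color image
make_uniform_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# disc(s) of given color on a bright background; returns image + true mask
make_disc_image <- function(h = 60, w = 60, centers = list(c(30, 30)),
                            radii = 12, rgb = c(60, 140, 50),
                            bg = c(250, 250, 250)) {
  img <- make_uniform_image(h, w, bg)
  mask <- matrix(0L, h, w)
  radii <- rep_len(radii, length(centers))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_along(centers)) {
    inside <- (rows - centers[[i]][1])^2 + (cols - centers[[i]][2])^2 <=
      radii[i]^2
    mask[inside] <- 1L
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[inside] <- rgb[ch]; img[, , ch] <- plane
    }
  }
  list(image = img, mask = mask)
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# ---- independent formula oracles (literal re-typings) --------------------

oracle_rmse <- function(y, yhat) sqrt(sum((y - yhat)^2) / length(y))

oracle_r2 <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# the 28 color-index formulas, re-typed independently of the package
oracle_features <- function(R, G, B) {
  s <- R + G + B
  r <- R / s; g <- G / s; b <- B / s
  c(R, G, B,
    R - G, R - B, G - B,
    R / G, R / B, G / B,
    (G - R) / (G + R),
    (G + B - R) / (2 * R), (G + B - R) / (2 * G), (G + B - R) / (2 * B),
    (R - G - B) / (R + B), (R - G - B) / (R + G), (R - G - B) / (G + B),
    (B - G - R) / (R + B), (B - G - R) / (B + G), (B - G - R) / (G + R),
    (2 * G - R - B) / (2 * G + R + B),
    (G - B) / (G + B), (G - B) * B / (R + G),
    r, g, b,
    r - g, r - b, g - b)
}

# SPAD-responsive mean leaf colors re-typed from the generator's response
# model, for building feature tables without rendering images
make_color_table <- function(n, seed = 1, noise = 0.5,
                             spad_mean = 42.05, spad_sd = 5.99) {
  cfg <- synthetic_config()
  spad <- sample_spad(cfg, n, seed = seed)
  s <- (spad - spad_mean) / spad_sd
  withr::with_seed(seed + 1, {
    colors <- tibble::tibble(
      mean_R = 90 - 25 * s + stats::rnorm(n, 0, noise),
      mean_G = 130 + 10 * s + stats::rnorm(n, 0, noise),
      mean_B = 60 + 8 * s + stats::rnorm(n, 0, noise)
    )
  })
  feature_table(colors, spad)
}

# cached default-condition synthetic dataset shared by the heavier tests
.fixture_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key, cfg) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_leaf_dataset(cfg)
  }
  .fixture_cache[[key]]
}
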