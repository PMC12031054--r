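test_that("load_image round-trips PNG pixels and handles degenerate files", {
  tmp <- withr::local_tempfile(fileext = ".png")
  img <- make_uniform_image(3, 3, c(10, 20, 30))
  png::writePNG(img / 255, tmp)
  back <- load_image(tmp)
  expect_equal(dim(back), c(3, 3, 3))
  expect_true(all(back[, , 1] == 10 & back[, , 2] == 20 & back[, , 3] == 30))

  one <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, dim = c(1, 1, 3)), one)
  expect_equal(dim(load_image(one)), c(1, 1, 3))

  bad <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:10), bad)
  expect_error(load_image(bad), class = "leafspad_io_error")
  expect_error(load_image("no/such/file.png"), class = "leafspad_io_error")
})

test_that("rgb_to_hsv follows the hexcone convention", {
  px <- function(rgb) {
    out <- rgb_to_hsv(make_uniform_image(1, 1, rgb))
    c(out[1, 1, 1], out[1, 1, 2], out[1, 1, 3])
  }
  expect_equal(px(c(255, 0, 0)), c(0, 1, 1))
  expect_equal(px(c(255, 255, 255)), c(0, 0, 1))
  expect_equal(px(c(0, 128, 0)), c(120, 1, 128 / 255))
  # achromatic black: hue and saturation defined as 0
  expect_equal(px(c(0, 0, 0)), c(0, 0, 0))
})

test_that("segment_leaf recovers a disc, keeps the largest object, fills holes", {
  fx <- make_disc_image()
  mk <- segment_leaf(fx$image)
  expect_s3_class(mk, "leaf_mask")
  expect_gte(mask_iou(mk$mask, fx$mask), 0.98)
  expect_equal(mk$area_px, sum(mk$mask))

  expect_error(segment_leaf(make_uniform_image(20, 20, c(255, 255, 255))),
               class = "leafspad_no_leaf")

  # two discs: only the larger is kept (areas ~400 px vs ~100 px)
  two <- make_disc_image(80, 80, centers = list(c(25, 25), c(60, 60)),
                         radii = c(11.3, 5.6))
  big <- make_disc_image(80, 80, centers = list(c(25, 25)), radii = 11.3)
  mk2 <- segment_leaf(two$image)
  expect_gte(mask_iou(mk2$mask, big$mask), 0.98)
  expect_lt(mk2$area_px, 500)

  # a bright hole inside the disc is filled into the ROI
  holed <- fx$image
  holed[28:32, 28:32, ] <- 250
  mk3 <- segment_leaf(holed)
  expect_true(all(mk3$mask[28:32, 28:32] == 1L))
})

test_that("segmentation is idempotent on the masked composite", {
  fx <- make_disc_image()
  mk <- segment_leaf(fx$image)
  # paint everything outside the mask with clean background
  comp <- fx$image
  for (ch in 1:3) {
    plane <- comp[, , ch]
    plane[mk$mask == 0L] <- 250
    comp[, , ch] <- plane
  }
  mk2 <- segment_leaf(comp)
  expect_identical(mk2$mask, mk$mask)
})

test_that("median_filter_roi removes salt noise, only inside the mask", {
  fx <- make_disc_image(h = 40, w = 40, centers = list(c(20, 20)),
                        radii = 10, rgb = c(50, 100, 40))
  img <- fx$image
  img[20, 20, ] <- c(255, 255, 255)  # salt pixel deep inside the disc
  out <- median_filter_roi(img, fx$mask, kernel = 3)
  expect_equal(out[20, 20, ], c(50, 100, 40))
  # pixels outside the mask are untouched even though they were filtered
  outside <- which(fx$mask == 0L)
  for (ch in 1:3) {
    expect_identical(out[, , ch][outside], img[, , ch][outside])
  }

  # constant region: median filtering is the identity
  flat <- make_uniform_image(20, 20, c(60, 140, 50))
  mask <- matrix(1L, 20, 20)
  expect_equal(median_filter_roi(flat, mask, kernel = 5), flat)

  # kernel 1 is the identity; even kernels are rejected
  expect_identical(median_filter_roi(img, fx$mask, kernel = 1), img)
  expect_error(median_filter_roi(img, fx$mask, kernel = 4),
               class = "leafspad_parameter_error")
  expect_error(median_filter_roi(img, fx$mask, kernel = -3),
               class = "leafspad_parameter_error")
})

test_that("filtered values come from the local neighborhood multiset", {
  withr::with_seed(42, {
    img <- array(sample(0:255, 30 * 30 * 3, replace = TRUE),
                 dim = c(30, 30, 3))
  })
  mask <- matrix(0L, 30, 30); mask[5:25, 5:25] <- 1L
  out <- median_filter_roi(img, mask, kernel = 3)
  for (i in 10:12) for (j in 10:12) for (ch in 1:3) {
    neigh <- img[(i - 1):(i + 1), (j - 1):(j + 1), ch]
    expect_true(out[i, j, ch] %in% neigh)
  }
})

test_that("mean_channels averages masked pixels only", {
  flat <- make_uniform_image(10, 10, c(60, 140, 50))
  mask <- matrix(1L, 10, 10)
  mc <- mean_channels(flat, mask)
  expect_equal(unlist(mc[, 1:3], use.names = FALSE), c(60, 140, 50))
  expect_equal(mc$n_pixels, 100)

  # half the masked pixels (0,0,0), half (100,200,50)
  img <- make_uniform_image(2, 2, c(0, 0, 0))
  img[1, , ] <- rep(c(100, 200, 50), each = 2)
  mc2 <- mean_channels(img, matrix(1L, 2, 2))
  expect_equal(unlist(mc2[, 1:3], use.names = FALSE), c(50, 100, 25))

  expect_error(mean_channels(flat, matrix(0L, 10, 10)),
               class = "leafspad_empty_roi")
})

test_that("mean_channels is invariant to the background color", {
  fx <- make_disc_image()
  base <- mean_channels(fx$image, fx$mask)
  for (seed in 1:10) {
    bg <- withr::with_seed(seed, stats::runif(3, 0, 255))
    img <- fx$image
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[fx$mask == 0L] <- bg[ch]
      img[, , ch] <- plane
    }
    expect_equal(mean_channels(img, fx$mask), base)
  }
})
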