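test_that("feature values are exact on hand-evaluated anchor colors", {
  gray <- compute_color_features(
    tibble::tibble(mean_R = 100, mean_G = 100, mean_B = 100))
  expect_equal(gray[["R-G"]], 0)
  expect_equal(gray[["R-B"]], 0)
  expect_equal(gray[["G-B"]], 0)
  expect_equal(gray[["R/G"]], 1)
  expect_equal(gray[["G/B"]], 1)
  expect_equal(gray[["(G+B-R)/(2G)"]], 0.5)
  expect_equal(gray[["r"]], 1 / 3)
  expect_equal(gray[["g"]], 1 / 3)
  expect_equal(gray[["r-g"]], 0)

  v <- compute_color_features(
    tibble::tibble(mean_R = 100, mean_G = 150, mean_B = 50))
  expect_equal(v[["R-B"]], 50)
  expect_equal(v[["G/B"]], 3)
  expect_equal(v[["(G+B-R)/(2G)"]], 100 / 300)
  expect_equal(v[["(2G-R-B)/(2G+R+B)"]], 150 / 450)
  expect_equal(v[["(G-B)B/(R+G)"]], 100 * 50 / 250)
  expect_equal(v[["r"]], 1 / 3)
  expect_equal(v[["g"]], 0.5)
  expect_equal(v[["b"]], 1 / 6)
})

test_that("zero denominators are flagged missing, never silently zero", {
  expect_warning(
    v <- compute_color_features(
      tibble::tibble(mean_R = 100, mean_G = 150, mean_B = 0)),
    class = "leafspad_zero_denominator")
  # every index dividing by B is undefined at B = 0
  expect_true(is.na(v[["R/B"]]))
  expect_true(is.na(v[["G/B"]]))
  expect_true(is.na(v[["(G+B-R)/(2B)"]]))
  finite_cols <- setdiff(color_feature_names(),
                         c("R/B", "G/B", "(G+B-R)/(2B)"))
  expect_true(all(is.finite(unlist(v[finite_cols]))))
})

test_that("features agree with an independently re-typed oracle", {
  withr::with_seed(7, {
    R <- stats::runif(1000, 1, 255)
    G <- stats::runif(1000, 1, 255)
    B <- stats::runif(1000, 1, 255)
  })
  got <- compute_color_features(
    tibble::tibble(mean_R = R, mean_G = G, mean_B = B))
  expect_identical(names(got), color_feature_names())
  for (i in c(1, 250, 500, 1000)) {
    expect_equal(unlist(got[i, ], use.names = FALSE),
                 oracle_features(R[i], G[i], B[i]), tolerance = 1e-12)
  }
  # full-table check at relative tolerance 1e-12
  oracle <- t(mapply(oracle_features, R, G, B))
  expect_lt(max(abs(as.matrix(got) - oracle) /
                  pmax(abs(oracle), 1e-9)), 1e-12)
})

test_that("ratio features are scale-covariant and differences scale", {
  withr::with_seed(11, {
    for (i in 1:20) {
      rgb <- stats::runif(3, 5, 200)
      k <- stats::runif(1, 0.3, 1.2)
      f1 <- compute_color_features(tibble::tibble(
        mean_R = rgb[1], mean_G = rgb[2], mean_B = rgb[3]))
      f2 <- compute_color_features(tibble::tibble(
        mean_R = k * rgb[1], mean_G = k * rgb[2], mean_B = k * rgb[3]))
      ratio_forms <- c("R/G", "R/B", "G/B", "(G-R)/(G+R)", "(G+B-R)/(2R)",
                       "(G+B-R)/(2G)", "(G+B-R)/(2B)", "(R-G-B)/(R+B)",
                       "(R-G-B)/(R+G)", "(R-G-B)/(G+B)", "(B-G-R)/(R+B)",
                       "(B-G-R)/(B+G)", "(B-G-R)/(G+R)",
                       "(2G-R-B)/(2G+R+B)", "(G-B)/(G+B)",
                       "r", "g", "b", "r-g", "r-b", "g-b")
      expect_equal(unlist(f2[ratio_forms]), unlist(f1[ratio_forms]),
                   tolerance = 1e-10)
      diff_forms <- c("R-G", "R-B", "G-B")
      expect_equal(unlist(f2[diff_forms]), k * unlist(f1[diff_forms]),
                   tolerance = 1e-10)
    }
  })
})

test_that("swapping R and B negates the antisymmetric differences", {
  withr::with_seed(13, {
    for (i in 1:20) {
      rgb <- stats::runif(3, 5, 250)
      f <- compute_color_features(tibble::tibble(
        mean_R = rgb[1], mean_G = rgb[2], mean_B = rgb[3]))
      fs <- compute_color_features(tibble::tibble(
        mean_R = rgb[3], mean_G = rgb[2], mean_B = rgb[1]))
      expect_equal(fs[["R-B"]], -f[["R-B"]])
      expect_equal(fs[["r-b"]], -f[["r-b"]], tolerance = 1e-12)
      # G-B under the swap becomes G-R of the original
      expect_equal(fs[["G-B"]], f[["G"]] - f[["R"]])
    }
  })
})

test_that("feature_table aligns, rejects mismatches and round-trips CSV", {
  colors <- tibble::tibble(mean_R = c(100, 90), mean_G = c(150, 140),
                           mean_B = c(50, 60))
  tbl <- feature_table(colors, c(40, 45))
  expect_equal(dim(tbl), c(2, 29))
  expect_identical(names(tbl), c("spad", color_feature_names()))

  empty <- feature_table(colors[0, ], numeric(0))
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 29)

  expect_error(feature_table(colors, 40),
               class = "leafspad_alignment_error")
  dup <- dplyr::mutate(colors, filename = c("a.png", "a.png"))
  expect_error(feature_table(dup, c(40, 45)),
               class = "leafspad_alignment_error")

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, tmp)
  expect_equal(as.data.frame(read_feature_table(tmp)), as.data.frame(tbl),
               tolerance = 1e-12)
  expect_error(read_feature_table(withr::local_tempfile(
    lines = "a,b\n1,2", fileext = ".csv")), class = "leafspad_schema_error")
})
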