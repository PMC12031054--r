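# a minimal deterministic model spec for protocol tests: predicts the
# training mean
mean_model_spec <- function() {
  fit <- function(X, y, seed) structure(list(m = mean(y)),
                                        class = "ls_test_meanmodel")
  list(null = list(fit = fit))
}
.S3method("predict", "ls_test_meanmodel",
          function(object, newdata, ...) rep(object$m, nrow(newdata)))

test_that("rmse and r_squared reproduce hand-evaluated cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 2), c(1, 1)), 1)
  expect_equal(rmse(5, 8), 3)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 8, 6, 2)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(0, 2), c(1, 1)), 0)
  expect_equal(r_squared(c(0, 2), c(2, 0)), -3)
  expect_error(r_squared(c(2, 2), c(1, 3)), class = "leafspad_undefined_r2")
  expect_error(rmse(1:3, 1:2), class = "leafspad_parameter_error")
  expect_error(rmse(numeric(0), numeric(0)),
               class = "leafspad_parameter_error")
})

test_that("metrics agree with re-typed formula oracles on random vectors", {
  withr::with_seed(33, {
    for (i in 1:50) {
      n <- sample(2:200, 1)
      y <- stats::rnorm(n, 40, 6)
      yh <- y + stats::rnorm(n)
      expect_equal(rmse(y, yh), oracle_rmse(y, yh), tolerance = 1e-12)
      expect_equal(r_squared(y, yh), oracle_r2(y, yh), tolerance = 1e-12)
    }
  })
})

test_that("the 80/20 split is exact, disjoint, exhaustive, reproducible", {
  sp <- split_80_20(520, seed = 9)
  expect_length(sp$train, 416)
  expect_length(sp$val, 104)
  expect_identical(sort(c(sp$train, sp$val)), 1:520)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(split_80_20(520, seed = 9), sp)
  expect_false(identical(split_80_20(520, seed = 10), sp))
  sp5 <- split_80_20(5, seed = 1)
  expect_length(sp5$val, 1)
  expect_error(split_80_20(3), class = "leafspad_parameter_error")
})

test_that("5-fold assignment covers each sample exactly once", {
  folds <- make_folds(520, k = 5, seed = 42)
  expect_length(folds, 520)
  expect_equal(unname(table(folds)), rep(104L, 5), ignore_attr = TRUE)
  expect_identical(make_folds(520, 5, 42), folds)
  expect_error(make_folds(3, 5), class = "leafspad_parameter_error")
})

test_that("a mean predictor cross-validates to zero R-squared", {
  tbl <- make_color_table(520, seed = 12, noise = 1)
  cv <- cross_validate(tbl, mean_model_spec(), k = 5, seed = 13)
  expect_equal(nrow(cv$results), 5 * 2)
  val_r2 <- cv$summary$mean_r_squared[cv$summary$split == "validation"]
  expect_lte(abs(val_r2), 0.05)
  train_r2 <- cv$summary$mean_r_squared[cv$summary$split == "train"]
  expect_equal(train_r2, 0, tolerance = 1e-12)
})

test_that("reported SDs equal hand-computed SDs over the fold lists", {
  tbl <- make_color_table(100, seed = 14, noise = 1)
  cv <- suppressMessages(cross_validate(
    tbl, spad_model_specs(models = "svr"), k = 5, seed = 15))
  per_fold <- cv$results[cv$results$split == "validation", ]
  expect_equal(
    cv$summary$sd_rmse[cv$summary$split == "validation"],
    stats::sd(per_fold$rmse))
  expect_equal(
    cv$summary$sd_r_squared[cv$summary$split == "validation"],
    stats::sd(per_fold$r_squared))
  # every sample in exactly one validation fold
  expect_equal(sort(unlist(lapply(1:5, function(f) which(cv$folds == f)))),
               1:100)
})

test_that("reordering samples within their folds changes nothing", {
  tbl <- make_color_table(60, seed = 16, noise = 1)
  cv1 <- cross_validate(tbl, mean_model_spec(), k = 5, seed = 17)
  expect_identical(make_folds(60, 5, 17), cv1$folds)
  # permute rows within each fold: identical partition, new sample order
  perm <- seq_len(60)
  withr::with_seed(18, {
    for (f in 1:5) {
      members <- which(cv1$folds == f)
      perm[members] <- sample(members)
    }
  })
  cv2 <- cross_validate(tbl[perm, ], mean_model_spec(), k = 5, seed = 17)
  expect_equal(cv2$results, cv1$results, tolerance = 1e-15)
  expect_equal(cv2$summary, cv1$summary, tolerance = 1e-15)
})

test_that("validation samples never influence preprocessing or fits", {
  tbl <- make_color_table(150, seed = 19, noise = 0.5)
  specs <- spad_model_specs(models = "svr")
  rep1 <- suppressMessages(evaluate_split(tbl, specs, seed = 20))
  sp <- attr(rep1, "split")
  # shuffle the SPAD values of the validation rows only
  tbl2 <- tbl
  tbl2$spad[sp$val] <- withr::with_seed(21, sample(tbl2$spad[sp$val]))
  rep2 <- suppressMessages(evaluate_split(tbl2, specs, seed = 20))
  r1 <- tibble::as_tibble(rep1); r2 <- tibble::as_tibble(rep2)
  # training metrics identical: the validation data played no role
  expect_equal(r2[r2$split == "train", ], r1[r1$split == "train", ],
               tolerance = 1e-12)
  # validation R-squared collapses from near-perfect to nothing
  expect_gt(r1$r_squared[r1$split == "validation"], 0.9)
  expect_lt(r2$r_squared[r2$split == "validation"], 0.2)
})

test_that("degenerate folds with constant SPAD are rejected", {
  tbl <- make_color_table(20, seed = 22, noise = 1)
  tbl$spad <- 42
  expect_error(cross_validate(tbl, mean_model_spec(), k = 5, seed = 23),
               class = "leafspad_fold_degenerate")
})

test_that("the comparison table carries the standard eight columns", {
  tbl <- make_color_table(100, seed = 24, noise = 1)
  cv <- suppressMessages(cross_validate(
    tbl, spad_model_specs(models = c("svr", "rvm")), k = 5, seed = 25))
  tab <- comparison_table(cv)
  expect_setequal(tab$model, c("svr", "rvm"))
  expect_identical(names(tab)[-1],
                   c("train_r2_pct", "train_r2_sd_pct", "train_rmse",
                     "train_rmse_sd", "val_r2_pct", "val_r2_sd_pct",
                     "val_rmse", "val_rmse_sd"))
  expect_true(all(tab$val_r2_pct > 90))  # planted response is recoverable
  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_md <- withr::local_tempfile(fileext = ".md")
  write_cv_report(cv, tmp_csv, tmp_md)
  expect_true(file.exists(tmp_csv) && file.exists(tmp_md))
  expect_match(readLines(tmp_md)[1], "^\\| model \\|")
})
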