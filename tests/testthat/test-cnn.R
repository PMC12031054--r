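# build a minimal trained-model shell with hand-set weights so the forward
# pass can be checked by hand arithmetic
hand_net <- function() {
  arch <- cnn_architecture(input_length = 5, conv_blocks = list(c(3, 1)),
                           fc_units = 2)
  params <- list(
    conv1 = list(W = array(c(-1, 0, 1), dim = c(3, 1, 1)), b = 0),
    bn1 = list(gamma = 1, beta = 0),
    fc1 = list(W = diag(2), b = c(0, 0)),
    output = list(W = matrix(c(1, 1), 2, 1), b = 0)
  )
  state <- list(bn1 = list(mean = 0, var = 1))
  structure(list(arch = arch, params = params, bn_state = state,
                 log = tibble::tibble(), best_epoch = 0L),
            class = "cnn_model")
}

test_that("the forward pass reproduces hand-computed activations", {
  net <- hand_net()
  x <- matrix(c(1, 2, 3, 4, 5), 1)
  # conv, same padding: out[t] = -x[t-1] + x[t+1] -> (2, 2, 2, 2, -4)
  # bn (inference, mean 0, var 1): /sqrt(1 + 1e-5)
  # relu -> (2,2,2,2,0)/s; pool(2,2) -> (2, 2)/s; head sums -> 4/s
  s <- sqrt(1 + 1e-5)
  expect_equal(predict(net, x), 4 / s, tolerance = 1e-6)
  pooled <- extract_features(net, x, tap = "pool1")
  expect_equal(drop(pooled), c(2, 2) / s, tolerance = 1e-6)
  convd <- extract_features(net, x, tap = "conv1")
  expect_equal(drop(convd), c(2, 2, 2, 2, -4), tolerance = 1e-9)
})

test_that("zero weights give zero output and batches equal row-wise passes", {
  net <- hand_net()
  net$params$conv1$W[] <- 0
  net$params$fc1$W[] <- 0
  net$params$output$W[] <- 0
  X <- matrix(stats::rnorm(15), 3, 5)
  expect_equal(predict(net, X), rep(0, 3))

  net2 <- hand_net()
  X <- withr::with_seed(5, matrix(stats::rnorm(25), 5, 5))
  batch <- predict(net2, X)
  single <- vapply(seq_len(5), function(i)
    predict(net2, X[i, , drop = FALSE]), 0)
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  arch <- cnn_architecture(input_length = 5,
                           conv_blocks = list(c(3, 4), c(2, 3)),
                           fc_units = 6)
  X <- withr::with_seed(2, matrix(stats::rnorm(40), 8, 5))
  y <- withr::with_seed(3, stats::rnorm(8))
  init <- withr::with_seed(4, leafspad:::cnn_init_params(arch))
  params <- init$params; state <- init$state

  loss_at <- function(params) {
    fwd <- leafspad:::cnn_forward(arch, params, state, X, training = TRUE)
    mean((fwd$pred - y)^2)
  }
  fwd <- leafspad:::cnn_forward(arch, params, state, X, training = TRUE)
  grads <- leafspad:::cnn_backward(arch, params, fwd,
                                   2 * (fwd$pred - y) / length(y))
  h <- 1e-5
  for (layer in c("conv1", "bn1", "conv2", "fc1", "output")) {
    for (field in names(grads[[layer]])) {
      g <- grads[[layer]][[field]]
      idx <- seq_len(min(3, length(g)))
      for (i in idx) {
        pp <- params; pp[[layer]][[field]][i] <- pp[[layer]][[field]][i] + h
        pm <- params; pm[[layer]][[field]][i] <- pm[[layer]][[field]][i] - h
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
        expect_equal(unname(g[i]), fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("the network fits a linear map of the components", {
  withr::with_seed(6, {
    X <- matrix(stats::rnorm(250), 50, 5)
    y <- drop(X %*% c(3, -1, 2, 0.5, 1)) + stats::rnorm(50, 0, 0.1)
  })
  m <- train_cnn(X, y, cnn_architecture(),
                 cnn_train_config(max_epochs = 1000, seed = 8))
  expect_lte(rmse(y, predict(m, X)), 0.5)
})

test_that("training is reproducible and respects the gradient clip", {
  withr::with_seed(10, {
    X <- matrix(stats::rnorm(150), 30, 5)
    y <- drop(X %*% c(1, 1, 0, 0, -1)) + stats::rnorm(30, 0.1)
  })
  cfg <- cnn_train_config(max_epochs = 120, seed = 21)
  m1 <- train_cnn(X, y, cnn_architecture(), cfg)
  m2 <- train_cnn(X, y, cnn_architecture(), cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$log$grad_norm <= 1 + 1e-9))
})

test_that("the learning rate steps down by 0.1 every 100 epochs", {
  withr::with_seed(14, {
    X <- matrix(stats::rnorm(100), 20, 5)
    y <- stats::rnorm(20)
  })
  cfg <- cnn_train_config(max_epochs = 201, patience = 10000, seed = 1)
  m <- train_cnn(X, y, cnn_architecture(), cfg)
  expect_equal(nrow(m$log), 201)
  expect_true(all(m$log$lr[1:100] == 0.01))
  expect_true(all(m$log$lr[101:200] == 0.001))
  expect_equal(m$log$lr[201], 1e-4)
})

test_that("early stopping halts within patience of the best epoch", {
  withr::with_seed(15, {
    X <- matrix(stats::rnorm(150), 30, 5)
    y <- drop(X %*% rep(1, 5))
    # validation targets unrelated to the inputs: no sustained improvement
    Xv <- matrix(stats::rnorm(50), 10, 5)
    yv <- stats::rnorm(10) * 100
  })
  cfg <- cnn_train_config(max_epochs = 500, patience = 10, seed = 2)
  m <- train_cnn(X, y, cnn_architecture(), cfg, X_val = Xv, y_val = yv)
  expect_lt(nrow(m$log), 500)
  expect_lte(nrow(m$log) - m$best_epoch, cfg$patience)
})

test_that("a heavy L2 penalty shrinks the weights", {
  withr::with_seed(16, {
    X <- matrix(stats::rnorm(150), 30, 5)
    y <- drop(X %*% c(2, 2, 2, 2, 2)) + stats::rnorm(30, 0, 0.1)
  })
  w_norm <- function(m) {
    sqrt(sum(vapply(c("conv1", "fc1", "output"),
                    function(l) sum(m$params[[l]]$W^2), 0)))
  }
  base <- cnn_train_config(max_epochs = 150, patience = 1000, seed = 3,
                           l2 = 0)
  heavy <- cnn_train_config(max_epochs = 150, patience = 1000, seed = 3,
                            l2 = 10)
  m0 <- train_cnn(X, y, cnn_architecture(), base)
  m1 <- train_cnn(X, y, cnn_architecture(), heavy)
  expect_lt(w_norm(m1), w_norm(m0))
})

test_that("NaN loss raises a training-diverged error naming the epoch", {
  X <- matrix(c(1e300, -1e300, 1e300, -1e300, 1e300,
                -1e300, 1e300, -1e300, 1e300, -1e300), 2, 5)
  y <- c(1e300, -1e300)
  expect_error(
    train_cnn(rbind(X, X, X), rep(y, 3), cnn_architecture(),
              cnn_train_config(max_epochs = 5, seed = 1)),
    class = "leafspad_training_diverged")
})

test_that("feature extraction taps are validated and consistent", {
  withr::with_seed(18, {
    X <- matrix(stats::rnorm(125), 25, 5)
    y <- drop(X %*% c(1, 0, 0, 1, 0))
  })
  m <- train_cnn(X, y, cnn_architecture_hybrid(),
                 cnn_train_config(max_epochs = 60, seed = 5))
  expect_error(extract_features(m, X, tap = "pool9"),
               class = "leafspad_config_error", regexp = "pool2")
  f_out <- extract_features(m, X, tap = "output")
  expect_equal(drop(f_out), predict(m, X))
  # identical rows give identical features
  Xdup <- X[c(1, 1, 2), ]
  fd <- extract_features(m, Xdup, tap = "pool2")
  expect_equal(fd[1, ], fd[2, ])
  expect_equal(ncol(fd), 32)  # 1 position x 32 filters after block 2
})
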