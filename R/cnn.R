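#' 1-D convolutional network architecture
#'
#' A small regression network over a short 1-D single-channel sequence (the
#' principal-component scores of one leaf). Each convolution block is
#' convolution ("same" padding) -> batch normalization -> ReLU -> max
#' pooling (window 2, stride 2; pooling is skipped when the running length
#' is below 2). The head is flatten -> dense(`fc_units`) -> ReLU ->
#' dense(1). With the default input length 5, one block maps lengths
#' 5 -> 2 and a second block 2 -> 1.
#'
#' The standalone SPAD network uses one block of sixteen 3-wide filters; the
#' hybrid feature extractors use two blocks (3-wide x 16, then 2-wide x 32),
#' available as [cnn_architecture_hybrid()].
#'
#' @param input_length Length of the input sequence (default 5 components).
#' @param conv_blocks List of `c(kernel_length, n_filters)` pairs.
#' @param fc_units Width of the dense hidden layer (default 32).
#' @return Object of class `cnn_architecture`, including the derived layer
#'   name sequence (`conv1`, `bn1`, `relu1`, `pool1`, ..., `flatten`,
#'   `fc1`, `relu_fc`, `output`).
#' @export
cnn_architecture <- function(input_length = 5L,
                             conv_blocks = list(c(3L, 16L)),
                             fc_units = 32L) {
  check_scalar_number(input_length, "input_length", lower = 1)
  check_scalar_number(fc_units, "fc_units", lower = 1)
  L <- as.integer(input_length)
  layers <- character(0)
  blocks <- list()
  for (i in seq_along(conv_blocks)) {
    blk <- conv_blocks[[i]]
    k <- as.integer(blk[1]); f <- as.integer(blk[2])
    if (k < 1L || k > L) {
      abort_leafspad(sprintf(
        "Block %d kernel length %d exceeds the feature-map length %d.",
        i, k, L), "leafspad_config_error")
    }
    pool <- L >= 2L
    blocks[[i]] <- list(kernel = k, filters = f, pool = pool)
    layers <- c(layers, paste0(c("conv", "bn", "relu"), i),
                if (pool) paste0("pool", i))
    if (pool) L <- L %/% 2L
  }
  layers <- c(layers, "flatten", "fc1", "relu_fc", "output")
  structure(list(input_length = as.integer(input_length),
                 blocks = blocks, fc_units = as.integer(fc_units),
                 out_length = L, layer_names = layers),
            class = "cnn_architecture")
}

#' @rdname cnn_architecture
#' @export
cnn_architecture_hybrid <- function(input_length = 5L, fc_units = 32L) {
  cnn_architecture(input_length,
                   conv_blocks = list(c(3L, 16L), c(2L, 32L)),
                   fc_units = fc_units)
}

#' CNN training configuration
#'
#' Full-batch Adam with a stepped learning-rate schedule (initial 0.01,
#' multiplied by 0.1 every 100 epochs), L2 weight penalty 0.001, global
#' gradient-norm clipping at 1.0, and early stopping on the validation loss
#' with patience 10. Weight initialization is seeded He-uniform, so training
#' is fully reproducible from `seed`.
#'
#' @param max_epochs Maximum training epochs (default 1000).
#' @param lr Initial learning rate.
#' @param lr_decay_factor,lr_decay_every Stepped decay: the rate is
#'   `lr * lr_decay_factor^floor((epoch - 1) / lr_decay_every)`.
#' @param l2 Coefficient of the L2 penalty on convolution and dense weights
#'   (biases and batch-norm parameters are not penalized).
#' @param clip_norm Global gradient-norm clipping threshold.
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement.
#' @param seed Integer seed for initialization (and the internal validation
#'   split when none is supplied).
#' @return Object of class `cnn_train_config`.
#' @export
cnn_train_config <- function(max_epochs = 1000L, lr = 0.01,
                             lr_decay_factor = 0.1, lr_decay_every = 100L,
                             l2 = 0.001, clip_norm = 1.0, patience = 10L,
                             seed = 1L) {
  check_scalar_number(lr, "lr", lower = 1e-12)
  check_scalar_number(l2, "l2", lower = 0)
  check_scalar_number(clip_norm, "clip_norm", lower = 1e-12)
  check_scalar_number(patience, "patience", lower = 1)
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 l2 = l2, clip_norm = clip_norm,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cnn_train_config")
}

# ---- parameter initialization -------------------------------------------

he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

cnn_init_params <- function(arch) {
  params <- list(); state <- list()
  C_in <- 1L; L <- arch$input_length
  for (i in seq_along(arch$blocks)) {
    blk <- arch$blocks[[i]]
    k <- blk$kernel; f <- blk$filters
    params[[paste0("conv", i)]] <- list(
      W = array(he_uniform(k * C_in * f, k * C_in), dim = c(k, C_in, f)),
      b = numeric(f))
    params[[paste0("bn", i)]] <- list(gamma = rep(1, f), beta = numeric(f))
    state[[paste0("bn", i)]] <- list(mean = numeric(f), var = rep(1, f))
    C_in <- f
    if (blk$pool) L <- L %/% 2L
  }
  flat <- L * C_in
  params$fc1 <- list(W = matrix(he_uniform(flat * arch$fc_units, flat),
                                flat, arch$fc_units),
                     b = numeric(arch$fc_units))
  params$output <- list(W = matrix(he_uniform(arch$fc_units, arch$fc_units),
                                   arch$fc_units, 1),
                        b = 0)
  list(params = params, state = state)
}

# ---- forward / backward --------------------------------------------------

conv1d_same <- function(X, W, b) {
  # X: m x L x C, W: k x C x F
  m <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  pad_l <- (k - 1L) %/% 2L; pad_r <- k - 1L - pad_l
  Xpad <- array(0, dim = c(m, L + k - 1L, C))
  Xpad[, pad_l + seq_len(L), ] <- X
  Wmat <- matrix(W, k * C, f)
  out <- array(0, dim = c(m, L, f))
  for (t in seq_len(L)) {
    win <- Xpad[, t:(t + k - 1L), , drop = FALSE]
    dim(win) <- c(m, k * C)
    out[, t, ] <- win %*% Wmat + matrix(b, m, f, byrow = TRUE)
  }
  list(out = out, Xpad = Xpad, pad_l = pad_l)
}

conv1d_backward <- function(dout, Xpad, W, pad_l, L) {
  m <- dim(dout)[1]; f <- dim(dout)[3]
  k <- dim(W)[1]; C <- dim(W)[2]
  Wmat <- matrix(W, k * C, f)
  dW <- matrix(0, k * C, f); db <- numeric(f)
  dXpad <- array(0, dim = dim(Xpad))
  for (t in seq_len(L)) {
    dt <- matrix(dout[, t, ], nrow = m)            # m x f
    win <- Xpad[, t:(t + k - 1L), , drop = FALSE]
    dim(win) <- c(m, k * C)
    dW <- dW + crossprod(win, dt)
    db <- db + colSums(dt)
    dwin <- dt %*% t(Wmat)                         # m x (k*C)
    dim(dwin) <- c(m, k, C)
    dXpad[, t:(t + k - 1L), ] <-
      dXpad[, t:(t + k - 1L), , drop = FALSE] + dwin
  }
  dX <- dXpad[, pad_l + seq_len(L), , drop = FALSE]
  list(dW = array(dW, dim = dim(W)), db = db, dX = dX)
}

bn_forward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  # X: m x L x F; normalize per filter over (m, L)
  d <- dim(X); f <- d[3]
  Xm <- matrix(X, d[1] * d[2], f)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean; va <- state$var
  }
  xhat <- sweep(sweep(Xm, 2, mu), 2, sqrt(va + eps), `/`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = array(out, dim = d), cache = list(xhat = xhat, mu = mu,
       va = va, eps = eps, dims = d), state = state)
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims; N <- d[1] * d[2]; f <- d[3]
  dY <- matrix(dout, N, f)
  xhat <- cache$xhat
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), N, f, byrow = TRUE) -
                sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
              2, inv_sd, `*`)
  list(dX = array(dX, dim = d), dgamma = dgamma, dbeta = dbeta)
}

maxpool2 <- function(X) {
  # X: m x L x F with L >= 2; window 2, stride 2, floor(L/2) outputs
  d <- dim(X); Lp <- d[2] %/% 2L
  a <- X[, 2 * seq_len(Lp) - 1L, , drop = FALSE]
  b <- X[, 2 * seq_len(Lp), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a, L_in = d[2])
}

maxpool2_backward <- function(dout, take_a, L_in, dims_in) {
  dX <- array(0, dim = dims_in)
  Lp <- dim(dout)[2]
  da <- dout * take_a
  db <- dout * !take_a
  dX[, 2 * seq_len(Lp) - 1L, ] <- da
  dX[, 2 * seq_len(Lp), ] <- dX[, 2 * seq_len(Lp), , drop = FALSE] + db
  dX
}

# Full forward pass. Returns predictions, per-layer activations (named by
# layer), caches for backprop, and (in training mode) updated BN state.
cnn_forward <- function(arch, params, state, X, training = FALSE) {
  m <- nrow(X)
  A <- array(X, dim = c(m, ncol(X), 1L))
  acts <- list(); caches <- list()
  for (i in seq_along(arch$blocks)) {
    blk <- arch$blocks[[i]]
    cv <- conv1d_same(A, params[[paste0("conv", i)]]$W,
                      params[[paste0("conv", i)]]$b)
    acts[[paste0("conv", i)]] <- cv$out
    caches[[paste0("conv", i)]] <- list(Xpad = cv$Xpad, pad_l = cv$pad_l,
                                        L = dim(cv$out)[2],
                                        dims_in = dim(A))
    bn <- bn_forward(cv$out, params[[paste0("bn", i)]]$gamma,
                     params[[paste0("bn", i)]]$beta,
                     state[[paste0("bn", i)]], training)
    if (training) state[[paste0("bn", i)]] <- bn$state
    acts[[paste0("bn", i)]] <- bn$out
    caches[[paste0("bn", i)]] <- bn$cache
    Ar <- pmax(bn$out, 0)
    acts[[paste0("relu", i)]] <- Ar
    caches[[paste0("relu", i)]] <- bn$out > 0
    if (blk$pool) {
      mp <- maxpool2(Ar)
      acts[[paste0("pool", i)]] <- mp$out
      caches[[paste0("pool", i)]] <- list(take_a = mp$take_a,
                                          L_in = mp$L_in,
                                          dims_in = dim(Ar))
      A <- mp$out
    } else {
      A <- Ar
    }
  }
  flat <- A; dim(flat) <- c(m, prod(dim(A)[2:3]))
  acts$flatten <- flat
  caches$flatten <- dim(A)
  Z1 <- flat %*% params$fc1$W +
    matrix(params$fc1$b, m, arch$fc_units, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  acts$fc1 <- Z1; acts$relu_fc <- A1
  caches$fc1 <- list(input = flat, mask = Z1 > 0)
  pred <- drop(A1 %*% params$output$W + params$output$b)
  acts$output <- matrix(pred, ncol = 1)
  list(pred = pred, acts = acts, caches = caches, state = state)
}

cnn_backward <- function(arch, params, fwd, dpred) {
  m <- length(dpred)
  grads <- list()
  A1 <- fwd$acts$relu_fc
  grads$output <- list(W = crossprod(A1, matrix(dpred, ncol = 1)),
                       b = sum(dpred))
  dA1 <- matrix(dpred, ncol = 1) %*% t(params$output$W)
  dZ1 <- dA1 * fwd$caches$fc1$mask
  grads$fc1 <- list(W = crossprod(fwd$caches$fc1$input, dZ1),
                    b = colSums(dZ1))
  dflat <- dZ1 %*% t(params$fc1$W)
  dA <- array(dflat, dim = fwd$caches$flatten)
  for (i in rev(seq_along(arch$blocks))) {
    blk <- arch$blocks[[i]]
    if (blk$pool) {
      pc <- fwd$caches[[paste0("pool", i)]]
      dA <- maxpool2_backward(dA, pc$take_a, pc$L_in, pc$dims_in)
    }
    dA <- dA * fwd$caches[[paste0("relu", i)]]
    bb <- bn_backward(dA, params[[paste0("bn", i)]]$gamma,
                      fwd$caches[[paste0("bn", i)]])
    grads[[paste0("bn", i)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cc <- fwd$caches[[paste0("conv", i)]]
    cb <- conv1d_backward(bb$dX, cc$Xpad, params[[paste0("conv", i)]]$W,
                          cc$pad_l, cc$L)
    grads[[paste0("conv", i)]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# flatten/apply helpers over the nested grad/param lists
grad_global_norm <- function(grads) {
  sqrt(sum(vapply(unlist(grads, recursive = FALSE),
                  function(g) sum(g^2), 0)))
}

scale_grads <- function(grads, s) {
  rapply(grads, function(g) g * s, how = "replace")
}

#' Train the 1-D CNN
#'
#' Full-batch gradient descent with Adam on mean squared error plus an L2
#' weight penalty. Each epoch performs one parameter update; the global
#' gradient norm is clipped to `cfg$clip_norm` (and its post-clip value
#' logged), the learning rate follows the stepped decay of
#' [cnn_train_config()], and training stops early once the validation loss
#' has not improved for `cfg$patience` epochs, restoring the best-epoch
#' weights. When no validation set is supplied, a seeded 80/20 split of the
#' training data is carved out for early stopping.
#'
#' @param X n x k numeric matrix (rows are samples).
#' @param y Numeric response of length n.
#' @param arch A [cnn_architecture()].
#' @param cfg A [cnn_train_config()].
#' @param X_val,y_val Optional validation split for early stopping.
#' @return Object of class `cnn_model` with trained parameters, batch-norm
#'   state, the per-epoch training log (`epoch`, `lr`, `train_loss`,
#'   `val_loss`, `grad_norm`), and the best epoch index.
#' @export
train_cnn <- function(X, y, arch = cnn_architecture(),
                      cfg = cnn_train_config(), X_val = NULL,
                      y_val = NULL) {
  X <- check_matrix_numeric(X)
  if (length(y) != nrow(X) || any(!is.finite(y))) {
    abort_leafspad("`y` must be finite and match the rows of `X`.",
                   "leafspad_validation_error")
  }
  if (ncol(X) != arch$input_length) {
    abort_leafspad(sprintf("Architecture expects input length %d, got %d.",
                           arch$input_length, ncol(X)),
                   "leafspad_schema_error")
  }
  init <- with_seed_ls(cfg$seed, {
    split <- NULL
    if (is.null(X_val)) {
      idx <- sample.int(nrow(X))
      n_val <- max(1L, round(0.2 * nrow(X)))
      split <- list(val = idx[seq_len(n_val)], tr = idx[-seq_len(n_val)])
    }
    c(cnn_init_params(arch), list(split = split))
  })
  if (!is.null(init$split)) {
    X_val <- X[init$split$val, , drop = FALSE]; y_val <- y[init$split$val]
    X <- X[init$split$tr, , drop = FALSE]; y <- y[init$split$tr]
  }
  params <- init$params; state <- init$state

  adam_m <- rapply(params, function(p) p * 0, how = "replace")
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  tstep <- 0

  log <- vector("list", cfg$max_epochs)
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  best_state <- state; wait <- 0L
  m <- nrow(X)

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$lr * cfg$lr_decay_factor^((epoch - 1L) %/% cfg$lr_decay_every)
    fwd <- cnn_forward(arch, params, state, X, training = TRUE)
    state <- fwd$state
    resid <- fwd$pred - y
    l2_term <- 0
    mse <- mean(resid^2)
    if (!is.finite(mse)) {
      abort_leafspad(sprintf("Training diverged (NaN loss) at epoch %d.",
                             epoch), "leafspad_training_diverged")
    }
    grads <- cnn_backward(arch, params, fwd, 2 * resid / m)
    # L2 penalty on weight tensors only
    if (cfg$l2 > 0) {
      for (layer in names(grads)) {
        if ("W" %in% names(grads[[layer]])) {
          W <- params[[layer]]$W
          grads[[layer]]$W <- grads[[layer]]$W + 2 * cfg$l2 * W
          l2_term <- l2_term + cfg$l2 * sum(W^2)
        }
      }
    }
    gn <- grad_global_norm(grads)
    if (gn > cfg$clip_norm) {
      grads <- scale_grads(grads, cfg$clip_norm / gn)
      gn <- cfg$clip_norm
    }
    tstep <- tstep + 1
    for (layer in names(grads)) {
      for (field in names(grads[[layer]])) {
        g <- grads[[layer]][[field]]
        adam_m[[layer]][[field]] <- beta1 * adam_m[[layer]][[field]] +
          (1 - beta1) * g
        adam_v[[layer]][[field]] <- beta2 * adam_v[[layer]][[field]] +
          (1 - beta2) * g^2
        mhat <- adam_m[[layer]][[field]] / (1 - beta1^tstep)
        vhat <- adam_v[[layer]][[field]] / (1 - beta2^tstep)
        params[[layer]][[field]] <- params[[layer]][[field]] -
          lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    val_pred <- cnn_forward(arch, params, state, X_val,
                            training = FALSE)$pred
    val_loss <- mean((val_pred - y_val)^2)
    log[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                   train_loss = mse + l2_term,
                                   val_loss = val_loss, grad_norm = gn)
    if (is.finite(val_loss) && val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_epoch <- epoch
      best_params <- params; best_state <- state; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  structure(list(
    arch = arch, config = cfg,
    params = best_params, bn_state = best_state,
    log = dplyr::bind_rows(log),
    best_epoch = best_epoch, best_val_loss = best_val
  ), class = "cnn_model")
}

#' Predict from a trained CNN
#'
#' Deterministic forward pass in inference mode (batch normalization uses
#' the stored running statistics); a batch of rows gives exactly the
#' concatenation of single-row passes.
#'
#' @param object A `cnn_model`.
#' @param newdata m x k matrix with the architecture's input length.
#' @param ... Unused.
#' @return Numeric vector of m predictions.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != object$arch$input_length) {
    abort_leafspad(sprintf("Network expects input length %d, got %d.",
                           object$arch$input_length, ncol(X)),
                   "leafspad_schema_error")
  }
  cnn_forward(object$arch, object$params, object$bn_state, X,
              training = FALSE)$pred
}

#' Extract intermediate-layer activations as features
#'
#' Runs the network in inference mode and returns the flattened activations
#' of the named layer, the feature interface used by the CNN-SVR and
#' CNN-RVM hybrids (tap `"pool2"` in the two-block architecture).
#'
#' @param object A `cnn_model`.
#' @param newdata m x k input matrix.
#' @param tap Layer name; see `object$arch$layer_names`.
#' @return m x d numeric feature matrix.
#' @export
extract_features <- function(object, newdata, tap = "pool2") {
  if (!tap %in% object$arch$layer_names) {
    abort_leafspad(sprintf("Unknown tap layer '%s'. Valid layers: %s.",
                           tap,
                           paste(object$arch$layer_names, collapse = ", ")),
                   "leafspad_config_error")
  }
  X <- as.matrix(newdata)
  fwd <- cnn_forward(object$arch, object$params, object$bn_state, X,
                     training = FALSE)
  a <- fwd$acts[[tap]]
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a)[1], prod(dim(a)[2:3]))
  a
}

#' @export
print.cnn_model <- function(x, ...) {
  blocks <- paste(vapply(x$arch$blocks, function(b)
    sprintf("%dx%d", b$kernel, b$filters), ""), collapse = ", ")
  cat(sprintf(
    "<cnn_model> input %d, conv blocks [%s], trained %d epochs (best %d)\n",
    x$arch$input_length, blocks, nrow(x$log), x$best_epoch))
  invisible(x)
}

#' @export
tidy.cnn_model <- function(x, ...) x$log

#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_lr = x$log$lr[nrow(x$log)])
}

#' Training-curve plot for a CNN fit
#' @param object A `cnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(y = "Loss (MSE + L2)", x = "Epoch", color = NULL) +
    ggplot2::theme_minimal()
}
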