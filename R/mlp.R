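# Multilayer-perceptron primitives: the spatial branch of the fusion model
# and the standalone MLP regressor used as a baseline and in the ablation
# harness. Hidden layers are rectified; the regressor adds a linear output
# unit.

#' Initialise parameters for a dense layer stack
#'
#' @param sizes Integer vector of layer widths, starting with the input
#'   width (e.g. `c(12, 25, 25, 25)` for a 3-layer encoder of width 25).
#' @return List of layers, each with `W` and `b`, initialised uniformly
#'   scaled by fan-in from the current RNG stream.
#' @export
init_mlp_params <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    s <- 1 / sqrt(sizes[l])
    list(W = matrix(runif(sizes[l + 1L] * sizes[l], -s, s),
                    nrow = sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

#' MLP forward pass
#'
#' Maps an input vector through a stack of rectified dense layers to its
#' hidden representation. Deterministic given fixed parameters.
#'
#' @param x Input vector (or matrix with one column per sample).
#' @param params List of layers, each with `W` and `b`.
#' @return The final-layer activation (vector, or matrix for matrix input).
#' @export
mlp_forward <- function(x, params) {
  a <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  for (layer in params) {
    if (ncol(layer$W) != nrow(a)) {
      stop_nibgm(sprintf("MLP input width %d does not match weights (%d)",
                         nrow(a), ncol(layer$W)), "nibgm_model_error")
    }
    a <- relu(layer$W %*% a + layer$b)
  }
  if (is.matrix(x)) a else drop(a)
}

# Batched forward with cache (pre-activations) for backprop.
mlp_forward_cache <- function(x, params) {
  a <- x
  zs <- vector("list", length(params))
  as <- vector("list", length(params) + 1L)
  as[[1L]] <- a
  for (l in seq_along(params)) {
    zs[[l]] <- params[[l]]$W %*% a + params[[l]]$b
    a <- relu(zs[[l]])
    as[[l + 1L]] <- a
  }
  list(out = a, zs = zs, as = as)
}

# Backward through the rectified stack; d_out is the gradient at the output
# activation. Returns per-layer gradients (no gradient wrt the input is
# needed by callers).
mlp_backward <- function(params, cache, d_out) {
  n_l <- length(params)
  grads <- vector("list", n_l)
  d <- d_out
  for (l in rev(seq_len(n_l))) {
    dz <- d * (cache$zs[[l]] > 0)
    grads[[l]] <- list(W = tcrossprod(dz, cache$as[[l]]), b = rowSums(dz))
    if (l > 1L) d <- crossprod(params[[l]]$W, dz)
  }
  grads
}

#' Fit an MLP regressor
#'
#' Trains a rectified MLP encoder with a linear output unit by Adam on the
#' mean-squared error, with Z-score normalization of inputs and target
#' fitted on the training data. This is the model used for the classical
#' MLP baseline and the PPG-only / PPG+absorbance ablation arms (3 layers
#' of width 25, 50 epochs, learning rate 0.01).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Numeric response (glucose, mmol/L).
#' @param width Hidden width.
#' @param n_layers Number of hidden layers.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (seeded shuffling each epoch).
#' @param seed Seed for initialisation and shuffling.
#' @return Object of class `nibgm_mlp` with elements `params` (encoder),
#'   `head` (linear output), `normalizer`, `loss_trace`.
#' @export
mlp_regressor <- function(x, y, width = 25, n_layers = 3, epochs = 50,
                          learning_rate = 0.01, batch_size = 32, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop_nibgm("x and y must have matching lengths", "nibgm_model_error")
  }
  if (nrow(x) < 2L) {
    stop_nibgm("need at least 2 training rows", "nibgm_model_error")
  }
  norm <- fit_normalizer(x, y)
  xn <- t(apply_normalizer(norm, x = x))  # features x samples
  yn <- apply_normalizer(norm, y = y)
  n <- length(yn)

  withr::with_seed(seed, {
    params <- c(init_mlp_params(c(nrow(xn), rep(width, n_layers))),
                list(list(W = matrix(runif(width, -1, 1) / sqrt(width),
                                     nrow = 1L),
                          b = 0)))
    vec <- unlist(params)
    adam <- adam_state(length(vec))
    loss_trace <- numeric(epochs)
    enc_idx <- seq_len(n_layers)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (bi in batches) {
        xb <- xn[, bi, drop = FALSE]
        yb <- yn[bi]
        cache <- mlp_forward_cache(xb, params[enc_idx])
        head <- params[[n_layers + 1L]]
        pred <- drop(head$W %*% cache$out) + head$b
        dpred <- matrix(2 * (pred - yb) / length(bi), nrow = 1L)
        g_head <- list(W = tcrossprod(dpred, cache$out), b = sum(dpred))
        d_out <- crossprod(head$W, dpred)
        g_enc <- mlp_backward(params[enc_idx], cache, d_out)
        gvec <- unlist(c(g_enc, list(g_head)))
        vec <- unlist(params)
        step <- adam_step(adam, gvec, learning_rate)
        adam <- step$state
        params <- utils::relist(vec - step$delta, params)
      }
      full <- mlp_forward_cache(xn, params[enc_idx])
      pred <- drop(params[[n_layers + 1L]]$W %*% full$out) +
        params[[n_layers + 1L]]$b
      loss_trace[ep] <- mean((pred - yn)^2)
    }
  })

  structure(list(params = params[enc_idx], head = params[[n_layers + 1L]],
                 normalizer = norm, loss_trace = loss_trace,
                 width = width, n_layers = n_layers),
            class = "nibgm_mlp")
}

#' @export
predict.nibgm_mlp <- function(object, newdata, ...) {
  xn <- t(apply_normalizer(object$normalizer, x = as.matrix(newdata)))
  h <- mlp_forward(xn, object$params)
  pred <- drop(object$head$W %*% h) + object$head$b
  invert_normalizer(object$normalizer, pred)
}

#' @export
print.nibgm_mlp <- function(x, ...) {
  cat(sprintf("MLP regressor: %d hidden layers of width %d; final MSE %.4g\n",
              x$n_layers, x$width, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

# Adam optimiser state and update (beta1 0.9, beta2 0.999, eps 1e-8).
adam_state <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, delta = lr * mhat / (sqrt(vhat) + state$eps))
}
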