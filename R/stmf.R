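#' Fuse branch representations into a glucose prediction
#'
#' The fusion head weights the MLP (spatial) and LSTM (temporal) branch
#' representations by the scalars `alpha1` and `alpha2`, concatenates them,
#' and maps the result through a fully connected linear output unit. With
#' `alpha1 = 0` the output is invariant to the MLP branch, and vice versa.
#'
#' @param h_mlp MLP branch representation (vector).
#' @param h_lstm LSTM branch representation (vector).
#' @param head List with `alpha` (two scalars), `W` (output weights, length
#'   `length(h_mlp) + length(h_lstm)`) and `b` (scalar bias).
#' @return Scalar prediction (normalized glucose scale).
#' @export
fuse_predict <- function(h_mlp, h_lstm, head) {
  w <- as.numeric(head$W)
  if (length(w) != length(h_mlp) + length(h_lstm)) {
    stop_nibgm("fusion weight length must match concatenated branches",
               "nibgm_model_error")
  }
  sum(w * c(head$alpha[1] * h_mlp, head$alpha[2] * h_lstm)) + head$b
}

# ---- internal: batched engine over padded day arrays ----------------------

# Convert a lagged dataset into padded arrays on the normalized scale:
# XF[[t]] is features x days, YP/Y/mask are Tmax x days.
lagged_arrays <- function(dataset, norm) {
  days <- dataset$days
  b <- length(days)
  t_len <- vapply(days, function(d) length(d$y), integer(1))
  tm <- max(t_len)
  p <- length(norm$x_mean)
  xf <- lapply(seq_len(tm), function(t) matrix(0, p, b))
  yp <- y <- mask <- matrix(0, tm, b)
  for (j in seq_len(b)) {
    xn <- t(apply_normalizer(norm, x = days[[j]]$x))
    for (t in seq_len(t_len[j])) xf[[t]][, j] <- xn[, t]
    yp[seq_len(t_len[j]), j] <- apply_normalizer(norm, y = days[[j]]$y_prev)
    y[seq_len(t_len[j]), j] <- apply_normalizer(norm, y = days[[j]]$y)
    mask[seq_len(t_len[j]), j] <- 1
  }
  list(xf = xf, yp = yp, y = y, mask = mask, t_len = t_len,
       day_names = names(days))
}

# Teacher-forced forward pass over padded arrays; optionally caches for
# backprop. Returns yhat (Tmax x B, normalized) and loss.
stmf_forward <- function(params, arr, keep_cache = FALSE) {
  hh <- nrow(params$lstm[[1]]$W) / 4L
  n_l <- length(params$lstm)
  b <- ncol(arr$mask)
  tm <- nrow(arr$mask)
  hs <- cs <- lapply(seq_len(n_l), function(.) matrix(0, hh, b))
  caches <- if (keep_cache) vector("list", tm)
  yhat <- matrix(0, tm, b)
  for (t in seq_len(tm)) {
    mc <- mlp_forward_cache(arr$xf[[t]], params$mlp)
    inp <- matrix(arr$yp[t, ], nrow = 1L)
    lc <- vector("list", n_l)
    for (l in seq_len(n_l)) {
      st <- lstm_layer_step_batch(params$lstm[[l]], inp, hs[[l]], cs[[l]])
      hs[[l]] <- st$h
      cs[[l]] <- st$c
      lc[[l]] <- st$cache
      inp <- st$h
    }
    zf <- rbind(params$alpha[1] * mc$out, params$alpha[2] * hs[[n_l]])
    yhat[t, ] <- drop(params$fc$W %*% zf) + params$fc$b
    if (keep_cache) {
      caches[[t]] <- list(mlp = mc, lstm = lc, h_mlp = mc$out,
                          h_lstm = hs[[n_l]], zf = zf)
    }
  }
  err <- (yhat - arr$y) * arr$mask
  n_valid <- sum(arr$mask)
  list(yhat = yhat, err = err, loss = sum(err^2) / n_valid,
       n_valid = n_valid, caches = caches)
}

# Full backward pass (BPTT); returns gradients in the parameter structure.
stmf_backward <- function(params, arr, fwd) {
  hh <- nrow(params$lstm[[1]]$W) / 4L
  n_l <- length(params$lstm)
  width <- nrow(params$mlp[[length(params$mlp)]]$W)
  b <- ncol(arr$mask)
  tm <- nrow(arr$mask)
  grads <- utils::relist(0 * unlist(params), params)
  dh_carry <- dc_carry <- lapply(seq_len(n_l), function(.) matrix(0, hh, b))
  for (t in rev(seq_len(tm))) {
    cache <- fwd$caches[[t]]
    dy <- matrix(2 * fwd$err[t, ] / fwd$n_valid, nrow = 1L)
    grads$fc$W <- grads$fc$W + tcrossprod(dy, cache$zf)
    grads$fc$b <- grads$fc$b + sum(dy)
    dzf <- crossprod(params$fc$W, dy)
    dz_m <- dzf[seq_len(width), , drop = FALSE]
    dz_l <- dzf[width + seq_len(hh), , drop = FALSE]
    grads$alpha[1] <- grads$alpha[1] + sum(dz_m * cache$h_mlp)
    grads$alpha[2] <- grads$alpha[2] + sum(dz_l * cache$h_lstm)
    g_mlp <- mlp_backward(params$mlp, cache$mlp, params$alpha[1] * dz_m)
    for (l in seq_along(g_mlp)) {
      grads$mlp[[l]]$W <- grads$mlp[[l]]$W + g_mlp[[l]]$W
      grads$mlp[[l]]$b <- grads$mlp[[l]]$b + g_mlp[[l]]$b
    }
    dx_above <- params$alpha[2] * dz_l
    for (l in rev(seq_len(n_l))) {
      dh <- dh_carry[[l]] + dx_above
      bk <- lstm_layer_step_backward(params$lstm[[l]], cache$lstm[[l]],
                                     dh, dc_carry[[l]])
      grads$lstm[[l]]$W <- grads$lstm[[l]]$W + bk$gW
      grads$lstm[[l]]$b <- grads$lstm[[l]]$b + bk$gb
      dh_carry[[l]] <- bk$dh_prev
      dc_carry[[l]] <- bk$dc_prev
      dx_above <- bk$dx
    }
  }
  grads
}

subset_arrays <- function(arr, cols) {
  t_len <- arr$t_len[cols]
  tm <- max(t_len)
  list(xf = lapply(arr$xf[seq_len(tm)],
                   function(m) m[, cols, drop = FALSE]),
       yp = arr$yp[seq_len(tm), cols, drop = FALSE],
       y = arr$y[seq_len(tm), cols, drop = FALSE],
       mask = arr$mask[seq_len(tm), cols, drop = FALSE],
       t_len = t_len, day_names = arr$day_names[cols])
}

# ---- fitting --------------------------------------------------------------

#' Fit the spatiotemporal multimodal fusion model
#'
#' Trains the two-branch glucose forecaster: a rectified MLP encodes the
#' 12-element optical feature vector (spatial branch) while a stacked LSTM
#' encodes the normalized glucose history through the lag-1 input
#' `y(t - 1)` (temporal branch); the branch representations are weighted by
#' learnable scalars `alpha1`, `alpha2`, concatenated, and mapped to the
#' prediction by a fully connected linear unit. Training minimises the MSE
#' with Adam (learning rate 0.01, 50 epochs by default, Table-style
#' settings: 3 LSTM layers and a 3-layer MLP, both of width 25). The
#' Z-score normalizer for features and glucose is fitted on the training
#' triples only. Updates use minibatches of whole day-sequences with a
#' seeded shuffle, so runs are bit-reproducible for a fixed seed; LSTM
#' state is reset at every day boundary.
#'
#' @param data A [build_lagged_dataset()] object (the training fold).
#' @param hidden_size LSTM hidden/cell width per layer.
#' @param n_lstm_layers Number of stacked LSTM layers.
#' @param mlp_width,n_mlp_layers MLP branch geometry.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_days Day-sequences per Adam update.
#' @param alpha_init Initial branch weights.
#' @param seed Seed for initialisation and batch shuffling.
#' @return An object of class `stmf_lstm` with components `params`,
#'   `normalizer`, `loss_trace` (training MSE on the normalized scale after
#'   each epoch), `fitted` (teacher-forced one-step training predictions,
#'   mmol/L), `config`, `data_summary`.
#' @seealso [predict.stmf_lstm()], [build_lagged_dataset()]
#' @examples
#' st <- generate_study(synth_config(seed = 1), 1, 2, 8)
#' ds <- build_lagged_dataset(study_features(st))
#' fit <- stmf_lstm(ds, epochs = 5, seed = 1)
#' fit
#' @export
stmf_lstm <- function(data, hidden_size = 25, n_lstm_layers = 3,
                      mlp_width = 25, n_mlp_layers = 3, epochs = 50,
                      learning_rate = 0.01, batch_days = 4,
                      alpha_init = c(0.5, 0.5), seed = 1L) {
  if (!inherits(data, "lagged_dataset")) {
    stop_nibgm("data must be a lagged_dataset", "nibgm_model_error")
  }
  if (!length(data$days)) {
    stop_nibgm("training dataset is empty", "nibgm_model_error")
  }
  stacked <- stack_lagged(data)
  norm <- fit_normalizer(stacked$x, stacked$y)
  arr <- lagged_arrays(data, norm)
  n_feat <- length(norm$x_mean)
  b_all <- length(arr$day_names)

  withr::with_seed(seed, {
    params <- list(
      lstm = c(list(init_lstm_params(1L, hidden_size)),
               lapply(seq_len(n_lstm_layers - 1L),
                      function(.) init_lstm_params(hidden_size, hidden_size))),
      mlp = init_mlp_params(c(n_feat, rep(mlp_width, n_mlp_layers))),
      alpha = alpha_init,
      fc = list(W = matrix(runif(mlp_width + hidden_size, -1, 1) /
                             sqrt(mlp_width + hidden_size), nrow = 1L),
                b = 0)
    )
    adam <- adam_state(length(unlist(params)))
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(b_all)
      batches <- split(ord, ceiling(seq_along(ord) / batch_days))
      for (cols in batches) {
        sub <- subset_arrays(arr, cols)
        fwd <- stmf_forward(params, sub, keep_cache = TRUE)
        if (!is.finite(fwd$loss)) {
          stop_nibgm(sprintf("training diverged (non-finite loss, epoch %d)",
                             ep), "nibgm_training_error")
        }
        grads <- stmf_backward(params, sub, fwd)
        step <- adam_step(adam, unlist(grads), learning_rate)
        adam <- step$state
        params <- utils::relist(unlist(params) - step$delta, params)
      }
      loss_trace[ep] <- stmf_forward(params, arr)$loss
    }
  })

  fwd <- stmf_forward(params, arr)
  fitted_mmol <- invert_normalizer(norm, fwd$yhat[arr$mask == 1])

  structure(list(
    params = params,
    normalizer = norm,
    loss_trace = loss_trace,
    fitted = fitted_mmol,
    reference = stacked$y,
    day = stacked$day,
    config = list(hidden_size = hidden_size, n_lstm_layers = n_lstm_layers,
                  mlp_width = mlp_width, n_mlp_layers = n_mlp_layers,
                  epochs = epochs, learning_rate = learning_rate,
                  batch_days = batch_days, seed = seed, tau = data$tau),
    data_summary = list(n_triples = length(stacked$y),
                        n_days = b_all,
                        feature_names = data$feature_names),
    call = match.call()
  ), class = "stmf_lstm")
}

# ---- prediction -----------------------------------------------------------

#' Predict glucose with a fitted fusion model
#'
#' Two modes. `"onestep"` is teacher-forced: each step uses the measured
#' previous glucose from the dataset. `"recursive"` emulates deployment:
#' each day's chain is anchored at a seed glucose value (by default the
#' day's first historical reference), and every subsequent step reuses the
#' model's own previous prediction as the historical glucose input, with
#' LSTM state carried across steps within a day and reset at day
#' boundaries. The first recursive step therefore equals the first one-step
#' prediction exactly.
#'
#' @param object A fitted [stmf_lstm()].
#' @param newdata A [build_lagged_dataset()] object.
#' @param type `"onestep"` or `"recursive"`.
#' @param seed_glucose Optional named vector (one value per day, mmol/L)
#'   anchoring each recursive chain; defaults to each day's first `y_prev`.
#' @param ... Unused.
#' @return Numeric vector of predictions in mmol/L, ordered day by day in
#'   `newdata` (matching `stack_lagged` ordering, i.e. the concatenated
#'   targets of each day).
#' @export
predict.stmf_lstm <- function(object, newdata,
                              type = c("onestep", "recursive"),
                              seed_glucose = NULL, ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "lagged_dataset")) {
    stop_nibgm("newdata must be a lagged_dataset", "nibgm_model_error")
  }
  arr <- lagged_arrays(newdata, object$normalizer)
  params <- object$params
  if (type == "onestep") {
    fwd <- stmf_forward(params, arr)
    return(invert_normalizer(object$normalizer, fwd$yhat[arr$mask == 1]))
  }
  # recursive rollout, batched across days
  hh <- object$config$hidden_size
  n_l <- object$config$n_lstm_layers
  b <- ncol(arr$mask)
  tm <- nrow(arr$mask)
  seeds <- if (is.null(seed_glucose)) {
    vapply(newdata$days, function(d) d$y_prev[1], numeric(1))
  } else if (length(seed_glucose) == 1L) {
    stats::setNames(rep(seed_glucose, b), arr$day_names)
  } else {
    seed_glucose[arr$day_names]
  }
  prev <- apply_normalizer(object$normalizer, y = as.numeric(seeds))
  hs <- cs <- lapply(seq_len(n_l), function(.) matrix(0, hh, b))
  yhat <- matrix(0, tm, b)
  for (t in seq_len(tm)) {
    h_mlp <- mlp_forward(arr$xf[[t]], params$mlp)
    inp <- matrix(prev, nrow = 1L)
    for (l in seq_len(n_l)) {
      st <- lstm_layer_step_batch(params$lstm[[l]], inp, hs[[l]], cs[[l]])
      hs[[l]] <- st$h
      cs[[l]] <- st$c
      inp <- st$h
    }
    zf <- rbind(params$alpha[1] * h_mlp, params$alpha[2] * hs[[n_l]])
    yhat[t, ] <- drop(params$fc$W %*% zf) + params$fc$b
    prev <- yhat[t, ]
  }
  invert_normalizer(object$normalizer, yhat[arr$mask == 1])
}

# ---- standard S3 methods --------------------------------------------------

#' @export
print.stmf_lstm <- function(x, ...) {
  cfg <- x$config
  cat("Spatiotemporal multimodal fused LSTM glucose model\n")
  cat(sprintf("  LSTM branch: %d layer(s) x %d units on lag-%d glucose history\n",
              cfg$n_lstm_layers, cfg$hidden_size, cfg$tau))
  cat(sprintf("  MLP branch:  %d layer(s) x %d units on %d optical features\n",
              cfg$n_mlp_layers, cfg$mlp_width,
              length(x$normalizer$x_mean)))
  cat(sprintf("  fusion weights alpha = (%.3f, %.3f)\n",
              x$params$alpha[1], x$params$alpha[2]))
  cat(sprintf("  trained %d epochs (Adam, lr %g) on %d triples / %d days; final MSE %.4g\n",
              cfg$epochs, cfg$learning_rate, x$data_summary$n_triples,
              x$data_summary$n_days, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.stmf_lstm <- function(object, ...) {
  res <- object$reference - object$fitted
  out <- list(
    config = object$config,
    n_parameters = length(unlist(object$params)),
    alpha = object$params$alpha,
    train_rmse = sqrt(mean(res^2)),
    train_mae = mean(abs(res)),
    loss_trace = object$loss_trace,
    data_summary = object$data_summary
  )
  class(out) <- "summary.stmf_lstm"
  out
}

#' @export
print.summary.stmf_lstm <- function(x, ...) {
  cat("STMF-LSTM model summary\n")
  cat(sprintf("  parameters: %d; fusion alpha = (%.3f, %.3f)\n",
              x$n_parameters, x$alpha[1], x$alpha[2]))
  cat(sprintf("  training (teacher-forced) RMSE %.3f, MAE %.3f mmol/L over %d triples\n",
              x$train_rmse, x$train_mae, x$data_summary$n_triples))
  cat(sprintf("  loss: %.4g (epoch 1) -> %.4g (epoch %d)\n",
              x$loss_trace[1], utils::tail(x$loss_trace, 1),
              length(x$loss_trace)))
  invisible(x)
}

#' @export
coef.stmf_lstm <- function(object, ...) {
  unlist(object$params)
}

#' @export
fitted.stmf_lstm <- function(object, ...) {
  object$fitted
}

#' @export
residuals.stmf_lstm <- function(object, ...) {
  object$reference - object$fitted
}

#' Plot the training loss trace of a fusion model
#'
#' @param x A fitted [stmf_lstm()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stmf_lstm <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training MSE (normalized)",
                 main = "STMF-LSTM training loss", ...)
  invisible(x)
}
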