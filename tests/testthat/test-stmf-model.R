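test_that("the LSTM cell reproduces hand-evaluated zero-weight cases", {
  p <- list(W = matrix(0, 4, 2), b = numeric(4))
  st <- lstm_cell_step(0, list(h = 0, c = 0), p)
  expect_equal(st$f, 0.5)
  expect_equal(st$i, 0.5)
  expect_equal(st$o, 0.5)
  expect_equal(st$c_tilde, 0)
  expect_equal(st$c, 0)
  expect_equal(st$h, 0)

  st2 <- lstm_cell_step(0, list(h = 0, c = 2), p)
  expect_equal(st2$c, 1.0)           # 0.5 * 2 + 0.5 * 0
  expect_equal(st2$h, 0.5 * tanh(1)) # ~0.380797

  expect_error(lstm_cell_step(c(1, 2), list(h = 0, c = 0), p),
               class = "nibgm_model_error")
})

test_that("the LSTM cell matches an independent scalar-loop oracle", {
  set.seed(101)
  for (k in 1:20) {
    hh <- 3L
    d <- sample(1:4, 1)
    params <- list(W = matrix(rnorm(4 * hh * (hh + d)), 4 * hh),
                   b = rnorm(4 * hh))
    state <- list(h = rnorm(hh), c = rnorm(hh))
    x <- rnorm(d)
    got <- lstm_cell_step(x, state, params)
    want <- lstm_cell_oracle(x, state, params)
    for (fld in c("h", "c", "f", "i", "o", "c_tilde")) {
      expect_equal(got[[fld]], want[[fld]], tolerance = 1e-12)
    }
  }
})

test_that("gates stay in their codomains and the cell update is linear", {
  set.seed(55)
  for (k in 1:100) {
    hh <- sample(1:6, 1)
    d <- sample(1:3, 1)
    params <- list(W = matrix(rnorm(4 * hh * (hh + d), sd = 2), 4 * hh),
                   b = rnorm(4 * hh, sd = 2))
    st <- lstm_cell_step(rnorm(d), list(h = rnorm(hh), c = rnorm(hh)), params)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    # tanh saturates to +/-1 in double precision for large arguments
    expect_true(all(abs(st$c_tilde) <= 1))
    expect_true(all(abs(tanh(st$c)) <= 1))
  }

  # input gate forced shut: c(t) = f * c(t-1) exactly
  hh <- 3L
  params <- list(W = matrix(rnorm(4 * hh * (hh + 1)), 4 * hh), b = rnorm(4 * hh))
  params$W[hh + seq_len(hh), ] <- 0
  params$b[hh + seq_len(hh)] <- -1e6
  cp <- rnorm(hh)
  st <- lstm_cell_step(rnorm(1), list(h = rnorm(hh), c = cp), params)
  expect_identical(st$c, st$f * cp)
})

test_that("MLP forward pass matches hand evaluation on a toy network", {
  zero <- list(list(W = matrix(0, 3, 2), b = numeric(3)))
  expect_equal(mlp_forward(c(1, -2), zero), rep(0, 3))

  # 2-unit chain with known weights: relu(W2 relu(W1 x + b1) + b2)
  p <- list(list(W = matrix(c(1, -1, 0.5, 2), 2, 2), b = c(0.1, -0.2)),
            list(W = matrix(c(1, 0, -1, 1), 2, 2), b = c(0, 0.3)))
  x <- c(0.4, -0.6)
  h1 <- pmax(p[[1]]$W %*% x + p[[1]]$b, 0)
  want <- pmax(p[[2]]$W %*% h1 + p[[2]]$b, 0)
  expect_equal(mlp_forward(x, p), drop(want))
  expect_identical(mlp_forward(x, p), mlp_forward(x, p))

  expect_error(mlp_forward(c(1, 2, 3), p), class = "nibgm_model_error")
})

test_that("fusion head gates branches through alpha and sums correctly", {
  hm <- c(1, 2)
  hl <- c(-1, 3)
  w <- c(0.5, -1, 2, 0.25)

  head0 <- list(alpha = c(0, 1), W = w, b = 0.1)
  expect_equal(fuse_predict(hm, hl, head0),
               fuse_predict(c(99, -5), hl, head0))
  head1 <- list(alpha = c(1, 0), W = w, b = 0.1)
  expect_equal(fuse_predict(hm, hl, head1),
               fuse_predict(hm, c(7, 7), head1))

  sum_head <- list(alpha = c(1, 1), W = rep(1, 4), b = 0)
  expect_equal(fuse_predict(hm, hl, sum_head), sum(hm) + sum(hl))

  expect_error(fuse_predict(hm, hl, list(alpha = c(1, 1), W = 1:3, b = 0)),
               class = "nibgm_model_error")
})

test_that("the Z-score normalizer centres, scales and round-trips", {
  set.seed(3)
  x <- matrix(rnorm(60, 5, 3), 20)
  y <- runif(20, 4, 9)
  norm <- fit_normalizer(x, y)
  xn <- apply_normalizer(norm, x = x)
  expect_lt(max(abs(colMeans(xn))), 1e-9)
  expect_equal(unname(apply(xn, 2, sd)), rep(1, 3), tolerance = 1e-9)
  expect_equal(invert_normalizer(norm, apply_normalizer(norm, y = y)), y,
               tolerance = 1e-12)

  x[, 2] <- 7  # constant column is epsilon-guarded and maps to zero
  norm2 <- fit_normalizer(x, y)
  expect_equal(unname(apply_normalizer(norm2, x = x)[, 2]), rep(0, 20))

  expect_error(fit_normalizer(matrix(numeric(0), 0, 3), numeric(0)),
               class = "nibgm_model_error")
})

test_that("lag-1 datasets group by day and never span a boundary", {
  x <- matrix(rnorm(10 * 12), 10)
  colnames(x) <- nibgm:::FEATURE_NAMES
  ds <- build_lagged_dataset(x, glucose = 1:10, day = rep("d1", 10))
  expect_length(ds$days, 1)
  expect_length(ds$days$d1$y, 9)
  expect_equal(ds$days$d1$y_prev, 1:9)
  expect_equal(ds$days$d1$y, 2:10)

  ds2 <- build_lagged_dataset(x, glucose = 1:10,
                              day = rep(c("d1", "d2"), each = 5))
  expect_equal(sum(vapply(ds2$days, function(d) length(d$y), integer(1))), 8)
  expect_false(1 %in% ds2$days$d2$y_prev[1])  # d2 starts from its own history
  expect_equal(ds2$days$d2$y_prev[1], 6)

  expect_warning(
    ds3 <- build_lagged_dataset(x[1:6, ], glucose = 1:6,
                                day = c(rep("d1", 5), "short")),
    "short")
  expect_length(ds3$days, 1)

  expect_error(build_lagged_dataset(x, glucose = 1:9, day = rep("d", 10)),
               class = "nibgm_model_error")
})

test_that("analytic BPTT gradients match numerical differentiation", {
  set.seed(17)
  n_feat <- 3L
  mkday <- function(t_n) list(
    x = matrix(rnorm(t_n * n_feat), t_n),
    y_prev = rnorm(t_n), y = rnorm(t_n), rows = seq_len(t_n))
  ds <- structure(list(days = list(d1 = mkday(4), d2 = mkday(3)),
                       tau = 1L, feature_names = paste0("f", 1:3)),
                  class = "lagged_dataset")
  norm <- structure(list(x_mean = rep(0, n_feat), x_sd = rep(1, n_feat),
                         y_mean = 0, y_sd = 1), class = "nibgm_normalizer")
  arr <- nibgm:::lagged_arrays(ds, norm)
  params <- list(
    lstm = list(init_lstm_params(1, 3), init_lstm_params(3, 3)),
    mlp = init_mlp_params(c(n_feat, 4, 4)),
    alpha = c(0.5, 0.5),
    fc = list(W = matrix(rnorm(7, sd = 0.5), 1), b = 0.1)
  )
  fwd <- nibgm:::stmf_forward(params, arr, keep_cache = TRUE)
  analytic <- unlist(nibgm:::stmf_backward(params, arr, fwd))

  vec <- unlist(params)
  loss_at <- function(v) {
    nibgm:::stmf_forward(utils::relist(v, params), arr)$loss
  }
  eps <- 1e-6
  idx <- sort(sample(length(vec), 60))
  numeric_g <- vapply(idx, function(j) {
    vp <- vec; vp[j] <- vp[j] + eps
    vm <- vec; vm[j] <- vm[j] - eps
    (loss_at(vp) - loss_at(vm)) / (2 * eps)
  }, numeric(1))
  expect_equal(analytic[idx], numeric_g, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("training learns a planted linear map, deterministically", {
  ft <- small_study_features(seed = 21)
  ds <- build_lagged_dataset(ft)

  fit <- stmf_lstm(ds, epochs = 30, batch_days = 1, seed = 4)
  expect_lt(tail(fit$loss_trace, 1), 0.2 * fit$loss_trace[1])
  expect_true(all(is.finite(fit$loss_trace)))

  fit2 <- stmf_lstm(ds, epochs = 30, batch_days = 1, seed = 4)
  expect_identical(coef(fit), coef(fit2))

  # a zero learning rate leaves the seeded initialisation untouched
  frozen <- stmf_lstm(ds, epochs = 5, learning_rate = 0, seed = 4)
  init_only <- stmf_lstm(ds, epochs = 0, seed = 4)
  expect_identical(coef(frozen), coef(init_only))
})

test_that("model accessors behave like standard fitted-model methods", {
  ft <- small_study_features(seed = 22)
  ds <- build_lagged_dataset(ft)
  fit <- stmf_lstm(ds, epochs = 8, seed = 2)

  expect_s3_class(fit, "stmf_lstm")
  expect_output(print(fit), "Spatiotemporal")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.stmf_lstm")
  expect_output(print(sm), "RMSE")
  expect_length(fitted(fit), length(residuals(fit)))
  expect_equal(fit$reference - fitted(fit), residuals(fit))
  expect_true(is.numeric(coef(fit)) && length(coef(fit)) > 1000)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("recursive prediction anchors at the seed and matches one-step at t = 1", {
  ft <- small_study_features(seed = 23)
  ds <- build_lagged_dataset(ft)
  fit <- stmf_lstm(ds, epochs = 8, seed = 3)

  one <- predict(fit, ds, type = "onestep")
  rec <- predict(fit, ds, type = "recursive")
  t_len <- vapply(ds$days, function(d) length(d$y), integer(1))
  first_idx <- cumsum(c(1, head(t_len, -1)))
  expect_equal(rec[first_idx], one[first_idx], tolerance = 1e-12)

  # an all-zero model with the normalizer centred at the seed value is a
  # fixed point: every recursive prediction equals the seed glucose
  seed_val <- 6.5
  zero_fit <- fit
  zero_fit$params <- utils::relist(0 * unlist(fit$params), fit$params)
  zero_fit$normalizer$y_mean <- seed_val
  zero_fit$normalizer$y_sd <- 1
  pred <- predict(zero_fit, ds, type = "recursive", seed_glucose = seed_val)
  expect_equal(pred, rep(seed_val, length(pred)))
})

test_that("the normalizer and fit never see held-out days", {
  ft <- small_study_features(seed = 24, n_subjects = 2, n_days = 2)
  ds <- build_lagged_dataset(ft)
  train_days <- names(ds$days)[1:3]
  test_day <- names(ds$days)[4]

  fit_a <- stmf_lstm(nibgm:::subset_days(ds, train_days), epochs = 5, seed = 9)

  # corrupt the held-out day wildly; training must be bit-identical
  ft2 <- ft
  sel <- ft2$subject_day == test_day
  ft2$glucose[sel] <- ft2$glucose[sel] * 10
  ft2[sel, nibgm:::FEATURE_NAMES] <- 999
  ds2 <- build_lagged_dataset(ft2)
  fit_b <- stmf_lstm(nibgm:::subset_days(ds2, train_days), epochs = 5, seed = 9)

  expect_identical(fit_a$normalizer, fit_b$normalizer)
  expect_identical(coef(fit_a), coef(fit_b))
})
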