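test_that("regression metrics follow their definitions", {
  ref <- c(5, 6, 7, 8)
  expect_equal(regression_metrics(ref, ref),
               c(rmse = 0, mae = 0, corr = 1, mard = 0))
  m <- regression_metrics(ref, ref + 1)
  expect_equal(unname(m[c("rmse", "mae")]), c(1, 1))

  # constant predictions: the correlation alone is undefined
  expect_warning(m2 <- regression_metrics(c(4, 6), c(5, 5)), "undefined")
  expect_equal(unname(m2["rmse"]), 1)
  expect_equal(unname(m2["mae"]), 1)
  expect_true(is.na(m2["corr"]))
  expect_equal(unname(m2["mard"]), 100 * (1 / 4 + 1 / 6) / 2,
               tolerance = 1e-9)  # 20.8333%

  expect_error(regression_metrics(1:3, 1:4), class = "nibgm_metric_error")
  expect_error(regression_metrics(c(5, 5), c(4, 6)),
               class = "nibgm_metric_error")  # constant reference
  expect_error(regression_metrics(c(-1, 5), c(4, 6)),
               class = "nibgm_metric_error")
})

test_that("RMSE dominates MAE and metrics are unit-consistent", {
  set.seed(9)
  for (k in 1:100) {
    n <- sample(2:40, 1)
    ref <- runif(n, 3, 20)
    pred <- ref + rnorm(n)
    m <- regression_metrics(ref, pred)
    expect_gte(m[["rmse"]], m[["mae"]])
    m_conv <- regression_metrics(ref * 18.016 / 18.016,
                                 pred * 18.016 / 18.016)
    expect_equal(m, m_conv, tolerance = 1e-9)
  }
})

test_that("identity predictions land entirely in Parkes zone A", {
  g <- seq(2, 28, length.out = 60)
  expect_true(all(parkes_zone(g, g) == "A"))
  expect_true(all(parkes_zone(g, g, variant = "type2") == "A"))
})

test_that("zone assignment agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  set.seed(41)
  ref <- runif(500, 2, 25)
  pred <- runif(500, 2, 25)
  got <- parkes_zone(ref, pred)
  want <- parkes_zone_oracle(ref * 18.016, pred * 18.016)
  expect_identical(got, want)
})

test_that("zone percentages always partition to 100", {
  set.seed(13)
  for (variant in c("type1", "type2")) {
    ref <- runif(200, 2, 28)
    pred <- pmax(0.1, ref + rnorm(200, sd = 4))
    z <- parkes_zone(ref, pred, variant)
    expect_true(all(z %in% c("A", "B", "C", "D", "E")))
    rep <- eval_report(ref, pred, variant)
    expect_equal(sum(rep$zones), 100, tolerance = 1e-9)
    expect_equal(sum(rep$zone_groups), 100, tolerance = 1e-9)
    expect_gte(rep$metrics[["rmse"]], rep$metrics[["mae"]])
  }
  expect_error(parkes_zone(c(1, -2), c(1, 1)), class = "nibgm_metric_error")
})

test_that("random folds are near-equal, disjoint, exhaustive and seeded", {
  f <- kfold_random(805, k = 10, seed = 2)
  expect_length(f, 805)
  expect_true(all(table(f) %in% c(80, 81)))
  expect_setequal(unique(f), 1:10)
  expect_identical(f, kfold_random(805, k = 10, seed = 2))
  expect_false(identical(f, kfold_random(805, k = 10, seed = 3)))

  loo <- kfold_random(7, k = 7, seed = 1)
  expect_equal(sort(unique(loo)), 1:7)
  expect_true(all(table(loo) == 1))

  expect_error(kfold_random(5, k = 6), class = "nibgm_config_error")
})

test_that("day-grouped folds keep whole subject-days together", {
  day <- rep(sprintf("d%02d", 1:16), each = 17)
  cv <- kfold_by_days(day, k = 8, days_per_fold = 2, seed = 5)
  expect_length(cv$fold, length(day))
  expect_true(all(table(cv$day_folds) == 2))
  per_day_folds <- tapply(cv$fold, day, function(x) length(unique(x)))
  expect_true(all(per_day_folds == 1))

  expect_error(kfold_by_days(rep(sprintf("d%d", 1:15), each = 2), k = 8),
               class = "nibgm_config_error")
})

test_that("baselines beat the null predictor on a learnable dataset", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("ranger")
  skip_if_not_installed("xgboost")
  set.seed(19)
  n <- 120
  x <- matrix(rnorm(n * 12), n, dimnames = list(NULL, nibgm:::FEATURE_NAMES))
  y <- 6 + 1.2 * x[, "da_nf_940"] + 0.8 * x[, "da_nt_850"] + rnorm(n, sd = 0.2)
  reports <- run_baselines(x, y, k = 10, seed = 7)
  null_rmse <- sqrt(mean((y - mean(y))^2))
  for (m in names(reports)) {
    expect_lt(reports[[m]]$metrics[["rmse"]], null_rmse)
  }

  reports2 <- run_baselines(x, y, k = 10, seed = 7)
  for (m in names(reports)) {
    expect_equal(reports[[m]]$metrics, reports2[[m]]$metrics,
                 tolerance = 1e-12)
  }

  expect_error(run_baselines(x[0, ], numeric(0)), class = "nibgm_model_error")
})

test_that("the ablation harness shares folds and echoes its method inputs", {
  ft <- small_study_features(seed = 30, n_subjects = 2, n_days = 2,
                             samples_per_day = 8)
  ab <- run_ablation(ft, k = 4, days_per_fold = 1, seed = 2, epochs = 4)

  expect_identical(ab$methods$A, nibgm:::PPG_FEATURE_NAMES)
  expect_identical(ab$methods$B, nibgm:::FEATURE_NAMES)
  expect_identical(ab$methods$C,
                   c(nibgm:::FEATURE_NAMES, "glucose_history"))

  # all three methods were evaluated under the same day-to-fold map
  cv <- kfold_by_days(ft$subject_day, k = 4, days_per_fold = 1, seed = 2)
  expect_identical(ab$day_folds, cv$day_folds)

  expect_equal(nrow(ab$predictions$AB), nrow(ft))
  expect_equal(nrow(ab$predictions$C), nrow(ft) - 4)  # one seed row per day
  expect_true(all(is.finite(ab$predictions$C$C)))
  for (m in c("A", "B", "C")) expect_s3_class(ab$reports[[m]], "eval_report")
})
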