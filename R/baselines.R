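#' Cross-validated classical regression baselines
#'
#' Runs the four reference models under seeded random k-fold
#' cross-validation on the 12-element feature table, pools the out-of-fold
#' predictions, and scores them once (metrics + Parkes zones). The
#' hyperparameters are the fixed study settings: MLP with 3 hidden layers
#' of width 25 trained by Adam (MSE, 50 epochs, lr 0.01); SVR with RBF
#' kernel, C = 10, gamma = 0.01, epsilon = 0.5; random forest with 100
#' trees of depth <= 5; XGBoost with 100 rounds, eta 0.1, depth 5,
#' subsample 0.8, colsample 0.8, alpha 0.5, lambda 0.5, min child weight 3.
#' SVR, random forest and XGBoost wrap the established e1071, ranger and
#' xgboost implementations; the MLP is the package's own Adam-trained
#' network. A model whose backing package is unavailable is skipped with a
#' warning.
#'
#' @param x Feature matrix or data frame (rows = samples, 12 columns).
#' @param glucose Reference glucose, mmol/L.
#' @param models Subset of `c("mlp", "svr", "rfr", "xgboost")`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and model training.
#' @param variant Parkes grid variant for the reports.
#' @return Named list of [eval_report()]s (class `baseline_reports`), with
#'   attribute `predictions` (data frame of pooled out-of-fold
#'   predictions).
#' @export
run_baselines <- function(x, glucose, models = c("mlp", "svr", "rfr", "xgboost"),
                          k = 10, seed = 1L, variant = "type1") {
  x <- as.matrix(x)
  if (nrow(x) == 0L || length(glucose) == 0L) {
    stop_nibgm("empty feature table", "nibgm_model_error")
  }
  if (nrow(x) != length(glucose)) {
    stop_nibgm("x and glucose must have matching lengths", "nibgm_model_error")
  }
  models <- match.arg(models, several.ok = TRUE)
  backing <- c(mlp = NA, svr = "e1071", rfr = "ranger", xgboost = "xgboost")
  for (m in models) {
    pkg <- backing[[m]]
    if (!is.na(pkg) && !requireNamespace(pkg, quietly = TRUE)) {
      warning(sprintf("skipping %s: package '%s' is not installed", m, pkg),
              call. = FALSE)
      models <- setdiff(models, m)
    }
  }
  folds <- kfold_random(nrow(x), k = k, seed = seed)
  preds <- matrix(NA_real_, nrow(x), length(models),
                  dimnames = list(NULL, models))
  for (f in seq_len(k)) {
    test <- folds == f
    xtr <- x[!test, , drop = FALSE]
    ytr <- glucose[!test]
    xte <- x[test, , drop = FALSE]
    for (m in models) {
      preds[test, m] <- withr::with_seed(seed + f, switch(
        m,
        mlp = {
          fit <- mlp_regressor(xtr, ytr, width = 25, n_layers = 3,
                               epochs = 50, learning_rate = 0.01,
                               seed = seed + f)
          predict(fit, xte)
        },
        svr = {
          norm <- fit_normalizer(xtr, ytr)
          fit <- e1071::svm(apply_normalizer(norm, x = xtr),
                            apply_normalizer(norm, y = ytr),
                            type = "eps-regression", kernel = "radial",
                            cost = 10, gamma = 0.01, epsilon = 0.5)
          invert_normalizer(norm, predict(fit, apply_normalizer(norm, x = xte)))
        },
        rfr = {
          d <- data.frame(y = ytr, xtr)
          fit <- ranger::ranger(y ~ ., data = d, num.trees = 100,
                                max.depth = 5, seed = seed + f,
                                num.threads = 1)
          predict(fit, data.frame(xte), num.threads = 1)$predictions
        },
        xgboost = {
          fit <- xgboost::xgboost(
            x = xtr, y = ytr, nrounds = 100, learning_rate = 0.1,
            max_depth = 5, subsample = 0.8, colsample_bytree = 0.8,
            reg_alpha = 0.5, reg_lambda = 0.5, min_child_weight = 3,
            objective = "reg:squarederror", verbosity = 0, nthreads = 1,
            seed = seed + f
          )
          predict(fit, xte)
        }
      ))
    }
  }
  reports <- lapply(stats::setNames(models, models), function(m) {
    eval_report(glucose, preds[, m], variant)
  })
  attr(reports, "predictions") <- data.frame(
    fold = folds, reference = glucose, preds, check.names = FALSE
  )
  class(reports) <- "baseline_reports"
  reports
}

#' @export
print.baseline_reports <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("== %s ==\n", toupper(m)))
    print(x[[m]])
  }
  invisible(x)
}
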