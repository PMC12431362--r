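#' Regression metrics for glucose prediction
#'
#' Computes the four standard agreement measures between reference and
#' predicted glucose: root mean square error and mean absolute error
#' (mmol/L), the Pearson correlation coefficient, and the mean absolute
#' relative difference `MARD = 100 * mean(|err| / reference)` in percent.
#'
#' @param reference Reference glucose, mmol/L (> 0).
#' @param predicted Predicted glucose, mmol/L.
#' @return Named vector `c(rmse, mae, corr, mard)`.
#' @examples
#' regression_metrics(c(4, 6), c(5, 5))  # rmse = mae = 1, mard = 20.83%
#' @export
regression_metrics <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop_nibgm("reference and predicted must have equal length",
               "nibgm_metric_error")
  }
  if (length(reference) < 2L) {
    stop_nibgm("need at least 2 pairs", "nibgm_metric_error")
  }
  if (any(reference <= 0)) {
    stop_nibgm("reference glucose must be strictly positive",
               "nibgm_metric_error")
  }
  if (sd(reference) < 1e-12) {
    stop_nibgm("correlation undefined: reference has zero variance",
               "nibgm_metric_error")
  }
  corr <- if (sd(predicted) < 1e-12) {
    warning("correlation undefined for constant predictions; returning NA",
            call. = FALSE)
    NA_real_
  } else {
    cor(reference, predicted)
  }
  err <- predicted - reference
  c(rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    corr = corr,
    mard = 100 * mean(abs(err) / reference))
}

#' Evaluation report for a set of predictions
#'
#' Bundles the regression metrics with the Parkes error-grid zone
#' percentages for one prediction set (typically pooled out-of-fold
#' predictions).
#'
#' @param reference,predicted Glucose values, mmol/L.
#' @param variant Parkes grid variant, `"type1"` or `"type2"`.
#' @return Object of class `eval_report`: list with `metrics`, `zones`
#'   (percentages A-E), `zone_groups` (A, B, C+D+E), `n`, `variant`.
#' @export
eval_report <- function(reference, predicted, variant = "type1") {
  metrics <- regression_metrics(reference, predicted)
  z <- parkes_zone(reference, predicted, variant)
  zones <- 100 * vapply(c("A", "B", "C", "D", "E"),
                        function(k) mean(z == k), numeric(1))
  structure(list(
    metrics = metrics,
    zones = zones,
    zone_groups = c(A = unname(zones["A"]), B = unname(zones["B"]),
                    CDE = unname(sum(zones[c("C", "D", "E")]))),
    n = length(reference),
    variant = variant
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "n = %d: RMSE %.3f, MAE %.3f mmol/L; CORR %.3f; MARD %.3f%%\n",
    x$n, m["rmse"], m["mae"], m["corr"], m["mard"]))
  cat(sprintf("Parkes zones (%s): A %.3f%%, B %.3f%%, C+D+E %.3f%%\n",
              x$variant, x$zone_groups["A"], x$zone_groups["B"],
              x$zone_groups["CDE"]))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(n = x$n, rmse = x$metrics[["rmse"]], mae = x$metrics[["mae"]],
             corr = x$metrics[["corr"]], mard = x$metrics[["mard"]],
             zone_a = x$zone_groups[["A"]], zone_b = x$zone_groups[["B"]],
             zone_cde = x$zone_groups[["CDE"]])
}
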