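#' Build a lag-1 supervised dataset grouped by day
#'
#' Converts a day-grouped feature table into supervised triples
#' `(xF(t), y(t - tau), y(t))` for the fusion model: within each day the
#' samples are kept time-ordered and each target from `t = tau + 1` onward
#' is paired with the feature vector at `t` and the reference glucose
#' `tau` steps earlier. No triple spans a day boundary; a day with `tau`
#' samples or fewer contributes no triples and raises a warning.
#'
#' @param features Either a numeric feature matrix (rows = samples,
#'   time-ordered within day), or a data frame containing the 12 feature
#'   columns plus `glucose` and `subject_day` (as produced by
#'   [study_features()]), in which case `glucose` and `day` are taken from
#'   it.
#' @param glucose Reference glucose per sample, mmol/L.
#' @param day Day (or subject-day) label per sample.
#' @param tau Lag order; the default 1 uses the previous glucose value as
#'   the historical input.
#' @return Object of class `lagged_dataset`: a list with `days` (per day:
#'   `x`, `y_prev`, `y`, `rows`), `tau` and `feature_names`.
#' @examples
#' st <- generate_study(synth_config(seed = 1), 1, 2, 5)
#' ft <- study_features(st)
#' ds <- build_lagged_dataset(ft)
#' length(ds$days)
#' @export
build_lagged_dataset <- function(features, glucose = NULL, day = NULL,
                                 tau = 1L) {
  tau <- check_count(tau, "tau")
  if (is.data.frame(features) && !is.null(features$glucose) &&
      !is.null(features$subject_day)) {
    glucose <- features$glucose
    day <- features$subject_day
    features <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  }
  features <- as.matrix(features)
  if (is.null(glucose) || is.null(day)) {
    stop_nibgm("glucose and day must be supplied (or present in the table)",
               "nibgm_model_error")
  }
  if (nrow(features) != length(glucose) || length(glucose) != length(day)) {
    stop_nibgm("features, glucose and day must have matching lengths",
               "nibgm_model_error")
  }
  day <- as.character(day)
  days <- list()
  for (d in unique(day)) {
    idx <- which(day == d)
    n <- length(idx)
    if (n <= tau) {
      warning(sprintf("day '%s' has %d sample(s); no lag-%d triples", d, n, tau),
              call. = FALSE)
      next
    }
    tgt <- idx[(tau + 1L):n]
    days[[d]] <- list(
      x = features[tgt, , drop = FALSE],
      y_prev = glucose[idx[seq_len(n - tau)]],
      y = glucose[tgt],
      rows = tgt
    )
  }
  structure(list(days = days, tau = tau,
                 feature_names = colnames(features)),
            class = "lagged_dataset")
}

#' @export
print.lagged_dataset <- function(x, ...) {
  n <- sum(vapply(x$days, function(d) length(d$y), integer(1)))
  cat(sprintf("Lag-%d dataset: %d triples over %d day(s)\n",
              x$tau, n, length(x$days)))
  invisible(x)
}

# Subset a lagged dataset by day names (used by CV drivers).
subset_days <- function(dataset, day_names) {
  structure(list(days = dataset$days[day_names], tau = dataset$tau,
                 feature_names = dataset$feature_names),
            class = "lagged_dataset")
}

# Stack all triples of a lagged dataset into matrices (rows = triples,
# ordered day by day).
stack_lagged <- function(dataset) {
  x <- do.call(rbind, lapply(dataset$days, function(d) d$x))
  list(x = x,
       y_prev = unlist(lapply(dataset$days, function(d) d$y_prev),
                       use.names = FALSE),
       y = unlist(lapply(dataset$days, function(d) d$y), use.names = FALSE),
       day = rep(names(dataset$days),
                 vapply(dataset$days, function(d) length(d$y), integer(1))))
}
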