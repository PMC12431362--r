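#' Random k-fold assignments
#'
#' Seeded shuffle into `k` disjoint, exhaustive folds whose sizes differ by
#' at most one (e.g. 805 samples into 10 folds of 80 or 81).
#'
#' @param n Number of samples (or a data frame, whose row count is used).
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Integer vector of fold labels (1..k) per sample.
#' @export
kfold_random <- function(n, k = 10, seed = 1L) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (k > n) {
    stop_nibgm(sprintf("k = %d exceeds the number of samples (%d)", k, n),
               "nibgm_config_error")
  }
  folds <- integer(n)
  withr::with_seed(seed, {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  })
  folds
}

#' Day-grouped k-fold assignments
#'
#' Assigns whole subject-days to folds so no acquisition day is split
#' across training and validation: with 16 subject-days, 8 folds of 2 days
#' each. The number of distinct days must equal `k * days_per_fold`.
#'
#' @param day Day (subject-day) label per sample.
#' @param k Number of folds.
#' @param days_per_fold Whole days per fold.
#' @param seed Shuffle seed.
#' @return List with `fold` (integer per sample) and `day_folds` (named
#'   integer: fold of each day).
#' @export
kfold_by_days <- function(day, k = 8, days_per_fold = 2, seed = 1L) {
  k <- check_count(k, "k")
  days_per_fold <- check_count(days_per_fold, "days_per_fold")
  day <- as.character(day)
  u <- unique(day)
  if (length(u) != k * days_per_fold) {
    stop_nibgm(sprintf(
      "found %d distinct days; day-grouped CV needs exactly k * days_per_fold = %d",
      length(u), k * days_per_fold), "nibgm_config_error")
  }
  withr::with_seed(seed, {
    shuffled <- sample(u)
  })
  day_folds <- stats::setNames(rep(seq_len(k), each = days_per_fold),
                               shuffled)
  list(fold = unname(day_folds[day]), day_folds = day_folds)
}
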