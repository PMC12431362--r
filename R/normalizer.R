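#' Z-score normalizer fitted on training data
#'
#' Computes per-dimension means and standard deviations of the feature
#' matrix and of the glucose response on the training rows only, so that
#' applying it yields zero-mean, unit-variance training columns. Standard
#' deviations below `1e-12` (constant columns) are replaced by 1, which
#' maps the column to exactly zero.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Glucose values, mmol/L.
#' @return Object of class `nibgm_normalizer`.
#' @export
fit_normalizer <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || length(y) < 1L) {
    stop_nibgm("cannot fit a normalizer on an empty training set",
               "nibgm_model_error")
  }
  if (nrow(x) != length(y)) {
    stop_nibgm("x and y must have matching lengths", "nibgm_model_error")
  }
  guard <- function(s) ifelse(!is.finite(s) | s < 1e-12, 1, s)
  structure(list(
    x_mean = colMeans(x),
    x_sd = guard(apply(x, 2, sd)),
    y_mean = mean(y),
    y_sd = guard(sd(y))
  ), class = "nibgm_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer A [fit_normalizer()] object.
#' @param x Feature matrix to scale (optional).
#' @param y Glucose values to scale (optional).
#' @return The scaled `x` (if only `x` given), scaled `y` (if only `y`),
#'   or a list with both.
#' @export
apply_normalizer <- function(normalizer, x = NULL, y = NULL) {
  xs <- if (!is.null(x)) {
    x <- as.matrix(x)
    sweep(sweep(x, 2, normalizer$x_mean, `-`), 2, normalizer$x_sd, `/`)
  }
  ys <- if (!is.null(y)) (y - normalizer$y_mean) / normalizer$y_sd
  if (is.null(ys)) return(xs)
  if (is.null(xs)) return(ys)
  list(x = xs, y = ys)
}

#' Invert a normalizer on predicted glucose
#'
#' Maps normalized predictions back to mmol/L;
#' `invert_normalizer(n, apply_normalizer(n, y = g))` is the identity.
#'
#' @param normalizer A [fit_normalizer()] object.
#' @param y_scaled Normalized glucose values.
#' @return Glucose in mmol/L.
#' @export
invert_normalizer <- function(normalizer, y_scaled) {
  y_scaled * normalizer$y_sd + normalizer$y_mean
}

#' @export
print.nibgm_normalizer <- function(x, ...) {
  cat(sprintf(
    "Z-score normalizer: %d feature dims; glucose mean %.3f, sd %.3f mmol/L\n",
    length(x$x_mean), x$y_mean, x$y_sd))
  invisible(x)
}
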