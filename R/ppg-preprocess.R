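#' PPG signal segment
#'
#' Lightweight container for a photoplethysmogram segment moving through the
#' preprocessing chain raw -> filtered -> detrended -> normalized. Each
#' preprocessing stage checks the incoming state, so stages cannot be
#' skipped or reordered silently.
#'
#' @param samples Amplitude sequence.
#' @param sampling_rate Sampling rate, Hz.
#' @param state Preprocessing state.
#' @return An object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, sampling_rate,
                        state = c("raw", "filtered", "detrended", "normalized")) {
  state <- match.arg(state)
  if (!is.numeric(samples) || length(samples) < 2L || anyNA(samples)) {
    stop_nibgm("samples must be a numeric vector without NAs",
               "nibgm_preprocessing_error")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, state = state),
            class = "ppg_segment")
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("PPG segment: %d samples at %g Hz (%s)\n",
              length(x$samples), x$sampling_rate, x$state))
  invisible(x)
}

check_state <- function(segment, expected, op) {
  if (!inherits(segment, "ppg_segment")) {
    stop_nibgm(sprintf("%s expects a ppg_segment", op),
               "nibgm_preprocessing_error")
  }
  if (!segment$state %in% expected) {
    stop_nibgm(sprintf("%s expects state %s, got '%s'",
                       op, paste(sQuote(expected), collapse = "/"),
                       segment$state),
               "nibgm_preprocessing_error")
  }
  invisible(segment)
}

#' Low-pass filter a raw PPG segment
#'
#' Sixth-order Butterworth low-pass design with a 15 Hz cutoff, applied
#' zero-phase (forward-backward), removing high-frequency noise without
#' shifting systolic peak timing.
#'
#' @param segment A raw [ppg_segment()].
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter design order.
#' @return The filtered segment (`state = "filtered"`).
#' @export
lowpass_filter <- function(segment, cutoff_hz = 15, order = 6) {
  check_state(segment, "raw", "lowpass_filter")
  fs <- segment$sampling_rate
  if (cutoff_hz >= fs / 2) {
    stop_nibgm(sprintf("cutoff %g Hz must be below Nyquist (%g Hz)",
                       cutoff_hz, fs / 2), "nibgm_config_error")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start-up transients of the IIR
  # forward-backward pass at both segment ends
  x <- segment$samples
  n <- length(x)
  npad <- min(n - 1L, 300L)
  xpad <- c(2 * x[1] - x[(npad + 1L):2],
            x,
            2 * x[n] - x[(n - 1L):(n - npad)])
  out <- signal::filtfilt(bf, xpad)[npad + seq_len(n)]
  ppg_segment(out, fs, "filtered")
}

# Local-maxima detector with greedy minimum-distance suppression and a
# prominence floor relative to the signal range. Shared by beat-foot
# detection (on the negated signal) and systolic peak detection.
find_local_peaks <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - p) >= min_dist)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  if (min_prom > 0) {
    prom <- vapply(keep, function(p) {
      left <- if (p > 1) {
        higher <- which(x[1:(p - 1)] > x[p])
        lo <- if (length(higher)) max(higher) + 1L else 1L
        min(x[lo:(p - 1)])
      } else x[p]
      right <- if (p < n) {
        higher <- which(x[(p + 1):n] > x[p])
        hi <- if (length(higher)) p + min(higher) - 1L else n
        min(x[(p + 1):hi])
      } else x[p]
      x[p] - max(left, right)
    }, numeric(1))
    keep <- keep[prom >= min_prom]
  }
  keep
}

#' Remove baseline drift with a cubic spline through beat feet
#'
#' Detects the foot (minimum) between consecutive preliminary beats, fits a
#' natural cubic spline through those per-beat minima, and subtracts it,
#' removing respiratory and motion baseline wander while preserving pulse
#' morphology. Preliminary beats are located on a drift-compensated proxy
#' (the signal minus a one-beat-scale running mean), so slow wander does
#' not mask the pulse prominence.
#'
#' @param segment A filtered [ppg_segment()].
#' @return The detrended segment (`state = "detrended"`).
#' @export
remove_baseline <- function(segment) {
  check_state(segment, "filtered", "remove_baseline")
  x <- segment$samples
  fs <- segment$sampling_rate
  w <- max(3L, round(1.2 * fs))
  run_mean <- stats::filter(x, rep(1 / w, w), sides = 2)
  run_mean <- as.numeric(run_mean)
  ok <- which(!is.na(run_mean))
  if (length(ok)) {
    run_mean[seq_len(ok[1] - 1L)] <- run_mean[ok[1]]
    run_mean[seq((utils::tail(ok, 1) + 1L), length.out =
                   length(x) - utils::tail(ok, 1))] <- run_mean[utils::tail(ok, 1)]
  } else {
    run_mean <- rep(mean(x), length(x))
  }
  proxy <- x - run_mean
  peaks <- find_local_peaks(proxy, min_dist = floor(fs * 60 / 180),
                           min_prom = 0.3 * diff(range(proxy)))
  feet <- integer(0)
  if (length(peaks) >= 2L) {
    feet <- vapply(seq_len(length(peaks) - 1L), function(i) {
      idx <- peaks[i]:peaks[i + 1]
      idx[which.min(x[idx])]
    }, integer(1))
  }
  if (length(feet) < 3L) {
    stop_nibgm(sprintf(
      "baseline removal needs >= 3 detectable beat minima (found %d)",
      length(feet)), "nibgm_preprocessing_error")
  }
  baseline <- spline(x = feet, y = x[feet], xout = seq_along(x),
                     method = "natural")$y
  ppg_segment(x - baseline, fs, "detrended")
}

#' Min-max normalize a detrended PPG segment
#'
#' Scales the segment to the unit interval, removing amplitude differences
#' between recordings.
#'
#' @param segment A detrended [ppg_segment()].
#' @return The normalized segment (`state = "normalized"`), values in 0-1.
#' @export
normalize_ppg <- function(segment) {
  check_state(segment, "detrended", "normalize_ppg")
  x <- segment$samples
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop_nibgm("cannot normalize a constant segment", "nibgm_degenerate_error")
  }
  ppg_segment((x - rng[1]) / diff(rng), segment$sampling_rate, "normalized")
}

#' Detect systolic peaks
#'
#' Finds systolic maxima on a normalized PPG segment: local maxima with a
#' minimum separation corresponding to 180 bpm and a prominence of at least
#' 0.3 of the normalized range.
#'
#' @param segment A normalized [ppg_segment()].
#' @return Strictly increasing peak sample indices (>= 2 of them).
#' @export
detect_peaks <- function(segment) {
  check_state(segment, "normalized", "detect_peaks")
  x <- segment$samples
  fs <- segment$sampling_rate
  peaks <- find_local_peaks(x, min_dist = floor(fs * 60 / 180),
                           min_prom = 0.3 * diff(range(x)))
  if (length(peaks) < 2L) {
    stop_nibgm(sprintf("fewer than 2 systolic peaks detected (%d)",
                       length(peaks)), "nibgm_feature_error")
  }
  peaks
}
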