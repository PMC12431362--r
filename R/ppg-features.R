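#' Heart-rate features from systolic peaks
#'
#' Converts consecutive peak intervals into an instantaneous heart-rate
#' series (`60 * fs / interval`, bpm) and returns its mean and sample
#' standard deviation; the latter serves as a heart-rate-variability proxy.
#'
#' @param peaks Strictly increasing peak indices (>= 2).
#' @param sampling_rate Sampling rate, Hz.
#' @return Named vector `c(hr_mu, hr_sigma)` in bpm (`hr_sigma` is 0 for a
#'   single interval).
#' @examples
#' heart_rate_features(c(1, 201, 401), 200)  # exactly 60 bpm
#' @export
heart_rate_features <- function(peaks, sampling_rate) {
  if (length(peaks) < 2L) {
    stop_nibgm("need >= 2 peaks for heart-rate features", "nibgm_feature_error")
  }
  if (any(diff(peaks) <= 0)) {
    stop_nibgm("peak indices must be strictly increasing", "nibgm_feature_error")
  }
  hr <- 60 * sampling_rate / diff(peaks)
  c(hr_mu = mean(hr), hr_sigma = if (length(hr) > 1L) sd(hr) else 0)
}

#' Divide a PPG signal into overlapping frames
#'
#' Splits the signal into `N = floor((L - Lframe) / (Lframe - Loverlap)) + 1`
#' frames of `Lframe` samples overlapping by `Loverlap`; any trailing
#' partial window is dropped. Short frames localise waveform features and
#' damp slow amplitude modulation (e.g. breathing); the 50% default overlap
#' preserves continuity at frame boundaries. With a 2000-sample signal and
#' the 400/200 defaults this yields 9 frames.
#'
#' @param segment A [ppg_segment()] (any state) or numeric vector.
#' @param l_frame Frame length in samples.
#' @param l_overlap Overlap between adjacent frames in samples.
#' @return A `Lframe x N` numeric matrix (one frame per column).
#' @export
frame_signal <- function(segment, l_frame = 400, l_overlap = 200) {
  x <- if (inherits(segment, "ppg_segment")) segment$samples else segment
  if (l_overlap < 0 || l_overlap >= l_frame) {
    stop_nibgm("l_overlap must satisfy 0 <= l_overlap < l_frame",
               "nibgm_config_error")
  }
  l <- length(x)
  if (l < l_frame) {
    stop_nibgm(sprintf("signal length %d is shorter than frame length %d",
                       l, l_frame), "nibgm_framing_error")
  }
  step <- l_frame - l_overlap
  n <- (l - l_frame) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step + 1L
  vapply(starts, function(s) x[s:(s + l_frame - 1L)], numeric(l_frame))
}

#' Kaiser-Teager energy sequence of a frame
#'
#' Evaluates the discrete Teager energy operator
#' `KTE(tau) = S(tau)^2 - S(tau + 1) * S(tau - 1)` over the interior samples
#' of a frame (endpoints excluded). For a pure discrete sinusoid of
#' amplitude A and angular frequency Omega the operator is constant at
#' `A^2 sin^2(Omega)`, which makes it an instantaneous energy tracker for
#' oscillatory signals such as the PPG pulse.
#'
#' @param frame Amplitude sequence of length >= 3.
#' @return Numeric vector of length `length(frame) - 2`.
#' @export
kte_sequence <- function(frame) {
  l <- length(frame)
  if (l < 3L) {
    stop_nibgm("KTE needs a frame of length >= 3", "nibgm_feature_error")
  }
  frame[2:(l - 1)]^2 - frame[3:l] * frame[1:(l - 2)]
}

#' Log-energy of a frame
#'
#' Decadic logarithm of the frame's total squared-sample energy, with a
#' small additive floor (`eps = 1e-12`) guarding all-zero frames.
#'
#' @param frame Non-empty amplitude sequence.
#' @param eps Energy floor.
#' @return A scalar: `log10(sum(frame^2) + eps)`.
#' @export
loge <- function(frame, eps = 1e-12) {
  if (!length(frame)) {
    stop_nibgm("loge needs a non-empty frame", "nibgm_feature_error")
  }
  log10(sum(frame^2) + eps)
}

#' Extract the 12-element optical feature vector
#'
#' Runs the full PPG chain on the 940 nm stable-segment AC channel
#' (low-pass filter, spline detrend, min-max normalization, systolic peak
#' detection) and assembles the feature vector: heart-rate mean and
#' standard deviation; mean and variance of the pooled interior
#' Kaiser-Teager energy values of all frames; mean and variance of the
#' per-frame log-energies; then the six differential absorbances. Framing
#' uses the first `ppg_samples` samples (default 2000, i.e. 10 s) of the
#' preprocessed stable segment.
#'
#' @param record A [device_record].
#' @param absorbances An `absorbance_set`; computed from `record` when NULL.
#' @param guard_s Stable-segment guard band, seconds.
#' @param ppg_samples Number of leading stable samples used for framing.
#' @param l_frame,l_overlap Framing parameters in samples.
#' @return Named numeric vector of length 12 (class `feature_vector`), in
#'   the fixed order `hr_mu, hr_sigma, kte_mu, kte_sigma, loge_mu,
#'   loge_sigma, da_nf_625, da_nt_625, da_nf_850, da_nt_850, da_nf_940,
#'   da_nt_940`.
#' @examples
#' rec <- generate_device_record(5.5, synth_config(seed = 5))
#' extract_features(rec)
#' @export
extract_features <- function(record, absorbances = NULL, guard_s = 1.0,
                             ppg_samples = 2000, l_frame = 400,
                             l_overlap = 200) {
  if (is.null(absorbances)) {
    absorbances <- compute_absorbance_set(record, guard_s)
  }
  segs <- extract_stable_segments(record, guard_s)
  seg940 <- segs[["940"]]
  if (is.null(seg940)) {
    stop_nibgm("record has no 940 nm phase for PPG feature extraction",
               "nibgm_feature_error")
  }
  fs <- attr(record, "sampling_rate")
  ac <- record$pd3_ac[seg940$start:seg940$end]

  seg <- ppg_segment(ac, fs, "raw")
  seg <- lowpass_filter(seg)
  seg <- remove_baseline(seg)
  seg <- normalize_ppg(seg)

  peaks <- detect_peaks(seg)
  hr <- heart_rate_features(peaks, fs)

  n_use <- min(ppg_samples, length(seg$samples))
  frames <- frame_signal(seg$samples[seq_len(n_use)], l_frame, l_overlap)
  kte_pool <- as.vector(apply(frames, 2, kte_sequence))
  loge_seq <- apply(frames, 2, loge)

  out <- c(hr,
           kte_mu = mean(kte_pool), kte_sigma = var(kte_pool),
           loge_mu = mean(loge_seq),
           loge_sigma = if (length(loge_seq) > 1L) var(loge_seq) else 0,
           unclass(absorbances))
  names(out) <- FEATURE_NAMES
  if (any(!is.finite(out))) {
    stop_nibgm("non-finite feature value", "nibgm_feature_error")
  }
  class(out) <- c("feature_vector", "numeric")
  out
}

#' Feature table for a whole study
#'
#' Applies [extract_features()] to every record of a synthetic (or loaded)
#' study and binds the results with the manifest metadata. Records failing
#' preprocessing or feature extraction are skipped with a warning reporting
#' the count.
#'
#' @param study An `nibgm_study`.
#' @param ... Passed to [extract_features()].
#' @return Data frame: `record`, `subject`, `day`, `subject_day`, `time_s`,
#'   `glucose`, then the 12 feature columns.
#' @export
study_features <- function(study, ...) {
  m <- study$manifest
  rows <- vector("list", nrow(m))
  failed <- character(0)
  for (i in seq_len(nrow(m))) {
    fv <- tryCatch(extract_features(study$records[[m$record[i]]], ...),
                   error = function(e) NULL)
    if (is.null(fv)) {
      failed <- c(failed, m$record[i])
    } else {
      rows[[i]] <- cbind(m[i, , drop = FALSE],
                         as.data.frame(as.list(unclass(fv))))
    }
  }
  if (length(failed)) {
    warning(sprintf("feature extraction failed for %d record(s): %s",
                    length(failed),
                    paste(utils::head(failed, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
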