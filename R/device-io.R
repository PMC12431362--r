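# Device acquisition I/O: fixed CSV dialect
#   header: time_s,led_nm,pd1_dc,pd2_dc,pd3_dc,pd3_ac
# comma-separated, UTF-8, '.' decimal, one row per sample at 200 Hz.

DEVICE_HEADER <- "time_s,led_nm,pd1_dc,pd2_dc,pd3_dc,pd3_ac"
DEVICE_COLUMNS <- strsplit(DEVICE_HEADER, ",")[[1]]

#' Construct and validate a device acquisition record
#'
#' A `device_record` holds one multichannel acquisition: uniformly sampled
#' time, the active LED wavelength per sample (piecewise constant in three
#' contiguous phases), the three DC intensity channels from the
#' near-reflection, far-reflection and transmission photodetectors, and the
#' transmitted AC PPG channel.
#'
#' @param time_s Time in seconds, strictly increasing, uniform.
#' @param led_nm Active LED wavelength per sample (nm).
#' @param pd1_dc,pd2_dc,pd3_dc DC intensities (near, far, transmission).
#' @param pd3_ac Transmitted PPG amplitude (arbitrary units).
#' @param sampling_rate Sampling rate in Hz; inferred from `time_s` when NULL.
#' @return A validated `device_record` data frame.
#' @export
device_record <- function(time_s, led_nm, pd1_dc, pd2_dc, pd3_dc, pd3_ac,
                          sampling_rate = NULL) {
  rec <- data.frame(time_s = time_s, led_nm = led_nm, pd1_dc = pd1_dc,
                    pd2_dc = pd2_dc, pd3_dc = pd3_dc, pd3_ac = pd3_ac)
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(time_s))
  }
  attr(rec, "sampling_rate") <- sampling_rate
  class(rec) <- c("device_record", "data.frame")
  validate_device_record(rec)
  rec
}

validate_device_record <- function(rec, warn_negative = TRUE) {
  n <- nrow(rec)
  if (n < 2L) {
    stop_nibgm("device record must contain at least 2 samples",
               "nibgm_format_error")
  }
  dt <- diff(rec$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop_nibgm(sprintf("time_s must be strictly increasing (sample %d)", bad),
               "nibgm_format_error")
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
    bad <- which.max(abs(dt - stats::median(dt))) + 1L
    stop_nibgm(sprintf("non-uniform timebase at sample %d", bad),
               "nibgm_format_error")
  }
  phases <- rle(rec$led_nm)
  if (length(phases$lengths) != 3L) {
    stop_nibgm(sprintf(
      "active_led must form exactly 3 contiguous phases (found %d)",
      length(phases$lengths)), "nibgm_format_error")
  }
  if (warn_negative) {
    seg <- tryCatch(extract_stable_segments(rec), error = function(e) NULL)
    if (!is.null(seg)) {
      for (sg in seg) {
        idx <- sg$start:sg$end
        for (ch in c("pd1_dc", "pd2_dc", "pd3_dc")) {
          neg <- idx[rec[[ch]][idx] <= 0]
          if (length(neg)) {
            warning(sprintf(
              "non-positive %s intensity in stable region at sample(s) %s",
              ch, paste(utils::head(neg, 5), collapse = ", ")),
              call. = FALSE)
          }
        }
      }
    }
  }
  invisible(rec)
}

#' Write a device record to CSV
#'
#' Writes the fixed-dialect CSV with full-precision decimal rendering
#' (17 significant digits), so that `read_record(write_record(x))`
#' round-trips bit-exactly.
#'
#' @param record A `device_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  validate_device_record(record, warn_negative = FALSE)
  num <- function(x) {
    s <- sprintf("%.17g", x)
    ok <- as.numeric(s) == x
    if (!all(ok)) s[!ok] <- sprintf("%.17e", x[!ok])
    s
  }
  lines <- paste(num(record$time_s), record$led_nm, num(record$pd1_dc),
                 num(record$pd2_dc), num(record$pd3_dc), num(record$pd3_ac),
                 sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(DEVICE_HEADER, lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read a device record from CSV
#'
#' Parses and fully validates a fixed-dialect acquisition CSV. Malformed
#' content (wrong header, non-numeric cells, non-uniform timebase) raises a
#' format error naming the offending line; non-positive DC intensities
#' inside stable regions raise a validation warning listing the samples.
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling rate; inferred from the timebase when NULL.
#' @return A validated `device_record`.
#' @export
read_record <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) {
    stop_nibgm(sprintf("file not found: %s", path), "nibgm_format_error")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop_nibgm(sprintf("empty file: %s", path), "nibgm_format_error")
  }
  if (!identical(header, DEVICE_HEADER)) {
    stop_nibgm(sprintf("line 1: header does not match dialect '%s'",
                       DEVICE_HEADER), "nibgm_format_error")
  }
  df <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop_nibgm(sprintf("unreadable CSV: %s",
                                           conditionMessage(e)),
                                   "nibgm_format_error")
  )
  if (nrow(df) == 0L) {
    stop_nibgm("file contains a header but no data rows", "nibgm_format_error")
  }
  out <- vector("list", length(DEVICE_COLUMNS))
  names(out) <- DEVICE_COLUMNS
  for (col in DEVICE_COLUMNS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_nibgm(sprintf("line %d: non-numeric value '%s' in column %s",
                         bad + 1L, df[[col]][bad], col),
                 "nibgm_format_error")
    }
    out[[col]] <- v
  }
  rec <- as.data.frame(out)
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(diff(rec$time_s))
  attr(rec, "sampling_rate") <- sampling_rate
  class(rec) <- c("device_record", "data.frame")
  validate_device_record(rec)
  rec
}

#' Select stable per-LED analysis segments
#'
#' Light-source switching injects transient artefacts around the phase
#' boundaries (near 15 s and 30 s in the 3 x 15 s layout); only the stable
#' portions between them are used for analysis. For each LED phase this
#' drops a guard band at both ends and returns the remaining sample range.
#' Indices are 1-based and inclusive.
#'
#' @param record A `device_record`.
#' @param guard_s Guard band dropped at each phase end, seconds.
#' @return A named list (one element per wavelength) of `stable_segment`
#'   objects: `wavelength`, `start`, `end` (inclusive sample indices).
#' @examples
#' rec <- generate_device_record(5.5, synth_config(seed = 2))
#' seg <- extract_stable_segments(rec)
#' vapply(seg, function(s) s$end - s$start + 1L, integer(1))
#' @export
extract_stable_segments <- function(record, guard_s = 1.0) {
  fs <- attr(record, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(record$time_s))
  phases <- rle(record$led_nm)
  ends <- cumsum(phases$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  guard_n <- as.integer(round(guard_s * fs))
  out <- list()
  for (i in seq_along(phases$values)) {
    len <- phases$lengths[i]
    if (len <= 2L * guard_n) {
      stop_nibgm(sprintf(
        "LED phase %g nm is too short (%.3g s) for guard bands of %g s",
        phases$values[i], len / fs, guard_s), "nibgm_segmentation_error")
    }
    seg <- structure(
      list(wavelength = phases$values[i],
           start = as.integer(starts[i] + guard_n),
           end = as.integer(ends[i] - guard_n)),
      class = "stable_segment"
    )
    out[[as.character(phases$values[i])]] <- seg
  }
  out
}

#' @export
print.stable_segment <- function(x, ...) {
  cat(sprintf("Stable segment: %g nm, samples %d-%d (%d samples)\n",
              x$wavelength, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}
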