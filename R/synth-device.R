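#' Generate one synthetic device acquisition
#'
#' Simulates a single finger-clip acquisition at a given glucose level:
#' three sequential LED phases (625, 850, 940 nm), each `led_phase_s`
#' seconds at `sampling_rate` Hz. The three DC channels follow the decadic
#' attenuation law per optical path, so intensities order
#' `near > far > trans` within every phase; a per-record absorbance drift
#' is drawn once per (wavelength, path) pair, emulating between-recording
#' coupling and tissue-state variation.
#' The AC channel is a continuous pulsatile PPG whose beat rate follows the
#' configured HR-glucose coupling with per-record and per-beat jitter, on
#' top of a slow respiratory-like wander. Short high-amplitude switching
#' transients are injected for 0.5 s after each LED switch (near 15 s and
#' 30 s); their sample indices are recorded in the `spike_idx` attribute so
#' stable-segment selection can be verified against them.
#'
#' @param glucose Reference glucose, mmol/L (> 0).
#' @param config A [synth_config()].
#' @param seed Seed for this record; defaults to `config$seed`.
#' @return A [device_record] data frame with attributes `sampling_rate`,
#'   `spike_idx` and `truth` (planted glucose, HR and differential
#'   absorbances including drift).
#' @examples
#' rec <- generate_device_record(5.5, synth_config(seed = 2))
#' head(rec)
#' @export
generate_device_record <- function(glucose, config, seed = config$seed) {
  if (!is.numeric(glucose) || length(glucose) != 1L || is.na(glucose) ||
      glucose <= 0) {
    stop_nibgm("glucose must be a single positive value (mmol/L)",
               "nibgm_domain_error")
  }
  validate_synth_config(config)
  fs <- config$sampling_rate
  n_phase <- round(config$led_phase_s * fs)
  n <- 3L * n_phase
  tt <- (seq_len(n) - 1) / fs

  withr::with_seed(seed, {
    drift <- matrix(
      if (config$absorbance_drift_sd > 0) {
        rnorm(9, 0, config$absorbance_drift_sd)
      } else 0,
      nrow = 3, ncol = 3,
      dimnames = list(as.character(WAVELENGTHS), PATHS)
    )

    led <- rep(WAVELENGTHS, each = n_phase)
    pd <- matrix(NA_real_, n, 3)
    for (w in seq_along(WAVELENGTHS)) {
      lam <- as.character(WAVELENGTHS[w])
      rows <- ((w - 1) * n_phase + 1):(w * n_phase)
      for (p in seq_along(PATHS)) {
        a <- config$baseline_attenuation[lam, PATHS[p]] +
          config$glucose_coefficient[lam, PATHS[p]] * glucose +
          drift[lam, PATHS[p]]
        pd[rows, p] <- config$i0[lam] * 10^(-a)
      }
    }
    if (config$noise_sd_dc > 0) {
      pd <- pd + matrix(rnorm(length(pd), 0, config$noise_sd_dc), n, 3)
    }

    # Pulsatile AC channel: two Gaussian lobes per beat.
    hr <- planted_heart_rate(config, glucose)
    if (config$hr_jitter_sd > 0) hr <- hr + rnorm(1, 0, config$hr_jitter_sd)
    hr <- min(max(hr, 45), 180)
    dur <- n / fs
    ps <- config$pulse_shape
    ac <- config$ac_wander_amp * sin(2 * pi * config$ac_wander_freq * tt)
    t0 <- -1  # start one beat early so the first visible beat is complete
    while (t0 < dur) {
      period <- 60 / hr
      if (config$beat_jitter_rel > 0) {
        period <- period * (1 + rnorm(1, 0, config$beat_jitter_rel))
      }
      for (lobe in list(c(ps$systolic_frac, ps$systolic_width, 1),
                        c(ps$dicrotic_frac, ps$dicrotic_width, ps$dicrotic_amp))) {
        ctr <- t0 + lobe[1] * period
        wid <- lobe[2] * period
        i1 <- max(1L, floor((ctr - 5 * wid) * fs) + 1L)
        i2 <- min(n, ceiling((ctr + 5 * wid) * fs) + 1L)
        if (i2 >= i1) {
          idx <- i1:i2
          ac[idx] <- ac[idx] + lobe[3] * exp(-((tt[idx] - ctr)^2) / (2 * wid^2))
        }
      }
      t0 <- t0 + period
    }
    if (config$noise_sd_ac > 0) ac <- ac + rnorm(n, 0, config$noise_sd_ac)

    # Switching transients: damped 25 Hz oscillation for 0.5 s per switch.
    spike_idx <- integer(0)
    for (b in config$led_phase_s * c(1, 2)) {
      idx <- which(tt >= b & tt < b + 0.5)
      spike_idx <- c(spike_idx, idx)
      burst <- exp(-(tt[idx] - b) / 0.1) * cos(2 * pi * 25 * (tt[idx] - b))
      for (p in 1:3) pd[idx, p] <- pd[idx, p] + 0.25 * mean(pd[idx, p]) * burst
      ac[idx] <- ac[idx] + 3 * burst
    }

    rec <- data.frame(
      time_s = tt, led_nm = led,
      pd1_dc = pd[, 1], pd2_dc = pd[, 2], pd3_dc = pd[, 3], pd3_ac = ac
    )
    attr(rec, "sampling_rate") <- fs
    attr(rec, "spike_idx") <- spike_idx
    attr(rec, "truth") <- list(
      glucose = glucose, hr_bpm = hr,
      delta_a = planted_absorbances(config, glucose, drift),
      drift = drift
    )
    class(rec) <- c("device_record", "data.frame")
    rec
  })
}

#' Generate a multi-subject, multi-day synthetic study
#'
#' Simulates a day-grouped study: per-subject baselines are drawn from a
#' seeded distribution, each subject contributes `n_days` days of
#' `samples_per_day` acquisitions along their glucose trajectory. The layout
#' (records grouped by subject-day) is the one required by day-grouped
#' cross-validation. With the defaults of 4 subjects, 4 days and 17 samples
#' per day, the study has 272 records over 16 subject-days.
#'
#' @param config A [synth_config()].
#' @param n_subjects,n_days,samples_per_day Study dimensions (each >= 1).
#' @return An object of class `nibgm_study`: list with `config`, `manifest`
#'   (one row per record: `record`, `subject`, `day`, `subject_day`,
#'   `time_s`, `glucose`) and `records` (named list of [device_record]s).
#' @examples
#' st <- generate_study(synth_config(seed = 3), n_subjects = 1,
#'                      n_days = 1, samples_per_day = 3)
#' st$manifest
#' @export
generate_study <- function(config, n_subjects = 4, n_days = 4,
                           samples_per_day = 17) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_days <- check_count(n_days, "n_days")
  samples_per_day <- check_count(samples_per_day, "samples_per_day")
  validate_synth_config(config)

  withr::with_seed(config$seed, {
    baselines <- rnorm(n_subjects, config$glucose_baseline, 0.4)
    lo <- config$glucose_range
    baselines <- pmin(pmax(baselines, lo[1] + 0.5), lo[2] - 0.5)
    n_rec <- n_subjects * n_days * samples_per_day
    seeds <- sample.int(.Machine$integer.max, n_subjects + n_rec)
  })

  records <- vector("list", n_rec)
  manifest <- vector("list", n_subjects)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    traj <- generate_glucose_trajectory(
      config, samples_per_day, n_days,
      baseline = baselines[s], seed = seeds[s]
    )
    manifest[[s]] <- data.frame(
      record = sprintf("r%04d", k + seq_len(nrow(traj))),
      subject = sprintf("S%02d", s),
      day = traj$day,
      subject_day = sprintf("S%02d_D%02d", s, traj$day),
      time_s = traj$time_s,
      glucose = traj$glucose
    )
    for (i in seq_len(nrow(traj))) {
      k <- k + 1L
      records[[k]] <- generate_device_record(
        traj$glucose[i], config, seed = seeds[n_subjects + k]
      )
    }
  }
  manifest <- do.call(rbind, manifest)
  names(records) <- manifest$record
  structure(
    list(config = config, manifest = manifest, records = records),
    class = "nibgm_study"
  )
}

#' @export
print.nibgm_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Synthetic acquisition study: %d records, %d subjects, %d subject-days\n",
    nrow(m), length(unique(m$subject)), length(unique(m$subject_day))
  ))
  cat(sprintf("  glucose %.1f-%.1f mmol/L; seed %d\n",
              min(m$glucose), max(m$glucose), x$config$seed))
  invisible(x)
}
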