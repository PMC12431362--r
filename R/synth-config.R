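#' Configuration for the synthetic acquisition simulator
#'
#' Builds the parameter set that drives every synthetic-data generator in the
#' package: daily glucose trajectories, per-LED DC intensities along the three
#' optical paths of the finger-clip geometry, and the pulsatile transmitted
#' PPG channel. The defaults emulate a sequential-illumination device with
#' three LEDs (625, 850, 940 nm) switched every 15 s, three photodetectors at
#' increasing source-detector separation (near reflection, far reflection,
#' transmission), and a 200 Hz sampling rate.
#'
#' DC intensities follow a decadic attenuation law
#' `I = I0(lambda) * 10^-(A0(lambda, path) + kappa(lambda, path) * g)` where
#' `g` is glucose in mmol/L, so each planted differential absorbance is an
#' affine, strictly increasing function of glucose. Heart rate is coupled
#' negatively to glucose (`hr = hr_baseline + hr_glucose_slope * g`, clipped
#' to 45-180 bpm), reflecting the inverse association between heart-rate
#' measures and glycaemia.
#'
#' @param i0 Named incident intensities per wavelength (arbitrary units).
#' @param baseline_attenuation 3x3 matrix of dimensionless absorbances,
#'   rows = wavelengths (625/850/940), columns = paths (near/far/trans).
#'   Must increase along near -> far -> trans so intensity ordering
#'   `near > far > trans` holds for all positive glucose.
#' @param glucose_coefficient 3x3 matrix of absorbance per (mmol/L), same
#'   layout; differential coefficients (far-near, trans-near) must be
#'   positive so planted differential absorbances increase with glucose.
#' @param heart_rate_baseline Intercept of the HR-glucose coupling (bpm).
#' @param hr_glucose_slope Slope of the coupling, bpm per (mmol/L); negative.
#' @param pulse_shape Two-lobe per-beat waveform parameters (systolic lobe +
#'   smaller delayed dicrotic lobe, both Gaussian), as fractions of the beat
#'   period plus the dicrotic relative amplitude.
#' @param noise_sd_dc Per-sample additive noise on the DC channels
#'   (intensity units).
#' @param noise_sd_ac Per-sample additive noise on the AC (PPG) channel.
#' @param absorbance_drift_sd Standard deviation of a per-record absorbance
#'   offset drawn independently for every (wavelength, path) pair,
#'   emulating between-recording variation in optical coupling, contact
#'   pressure and tissue state. This, not the fast DC noise (which averages
#'   out over the 2600-sample stable segment), is what limits
#'   differential-absorbance recovery; the default is calibrated so that
#'   regression on the optical features alone lands in the error regime
#'   around 1 mmol/L observed for wearable optical devices.
#' @param hr_jitter_sd Per-record heart-rate offset (bpm).
#' @param beat_jitter_rel Per-beat relative jitter of the beat period.
#' @param ac_wander_amp,ac_wander_freq Amplitude and frequency (Hz) of a slow
#'   respiratory-like baseline wander added to the AC channel so baseline
#'   removal has real work to do.
#' @param sampling_rate Sampling rate in Hz.
#' @param led_phase_s Seconds each LED is active.
#' @param glucose_range Plausible glucose range (lo, hi) in mmol/L used to
#'   clip trajectories; the non-diabetic default is 3.9-9.3.
#' @param glucose_baseline Subject fasting baseline (mmol/L).
#' @param excursion_mmol Peak amplitude of each postprandial excursion
#'   (mmol/L).
#' @param meal_times_h Meal times in hours of the day.
#' @param glucose_noise_sd Stationary standard deviation of the AR(1)
#'   trajectory noise (mmol/L).
#' @param glucose_noise_rho AR(1) autocorrelation of the trajectory noise.
#' @param day_window_h Sampling window within a day, hours (start, end).
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$glucose_range
#' @export
synth_config <- function(i0 = c("625" = 4000, "850" = 4200, "940" = 3800),
                         baseline_attenuation = default_baseline_attenuation(),
                         glucose_coefficient = default_glucose_coefficient(),
                         heart_rate_baseline = 75,
                         hr_glucose_slope = -2,
                         pulse_shape = list(systolic_frac = 0.30,
                                            systolic_width = 0.10,
                                            dicrotic_frac = 0.62,
                                            dicrotic_width = 0.14,
                                            dicrotic_amp = 0.35),
                         noise_sd_dc = 2.0,
                         noise_sd_ac = 0.01,
                         absorbance_drift_sd = 0.013,
                         hr_jitter_sd = 3,
                         beat_jitter_rel = 0.02,
                         ac_wander_amp = 0.10,
                         ac_wander_freq = 0.2,
                         sampling_rate = 200,
                         led_phase_s = 15,
                         glucose_range = c(3.9, 9.3),
                         glucose_baseline = 5.2,
                         excursion_mmol = 2.0,
                         meal_times_h = c(7.5, 12.5, 18.5),
                         glucose_noise_sd = 0.15,
                         glucose_noise_rho = 0.6,
                         day_window_h = c(7, 21),
                         seed = 1L) {
  cfg <- list(
    i0 = i0,
    baseline_attenuation = baseline_attenuation,
    glucose_coefficient = glucose_coefficient,
    heart_rate_baseline = heart_rate_baseline,
    hr_glucose_slope = hr_glucose_slope,
    pulse_shape = pulse_shape,
    noise_sd_dc = noise_sd_dc,
    noise_sd_ac = noise_sd_ac,
    absorbance_drift_sd = absorbance_drift_sd,
    hr_jitter_sd = hr_jitter_sd,
    beat_jitter_rel = beat_jitter_rel,
    ac_wander_amp = ac_wander_amp,
    ac_wander_freq = ac_wander_freq,
    sampling_rate = sampling_rate,
    led_phase_s = led_phase_s,
    glucose_range = glucose_range,
    glucose_baseline = glucose_baseline,
    excursion_mmol = excursion_mmol,
    meal_times_h = meal_times_h,
    glucose_noise_sd = glucose_noise_sd,
    glucose_noise_rho = glucose_noise_rho,
    day_window_h = day_window_h,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

WAVELENGTHS <- c(625, 850, 940)
PATHS <- c("near", "far", "trans")

#' Default per-(wavelength, path) optical parameters
#'
#' `default_baseline_attenuation()` returns the glucose-independent decadic
#' absorbance of each (wavelength, path) pair; it increases along
#' near -> far -> trans so intensity ordering holds.
#' `default_glucose_coefficient()` returns the absorbance added per mmol/L
#' of glucose, larger for longer paths and for 940 nm, so every
#' differential absorbance rises with glucose.
#'
#' @return A 3x3 matrix, rows = wavelengths (625/850/940 nm),
#'   columns = paths (near/far/trans).
#' @export
default_baseline_attenuation <- function() {
  matrix(c(0.35, 0.62, 1.05,
           0.30, 0.55, 0.95,
           0.28, 0.52, 0.90),
         nrow = 3, byrow = TRUE,
         dimnames = list(as.character(WAVELENGTHS), PATHS))
}

#' @rdname default_baseline_attenuation
#' @export
default_glucose_coefficient <- function() {
  matrix(c(0.002, 0.006, 0.010,
           0.003, 0.009, 0.015,
           0.004, 0.012, 0.020),
         nrow = 3, byrow = TRUE,
         dimnames = list(as.character(WAVELENGTHS), PATHS))
}

validate_synth_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) {
    stop_nibgm("sampling_rate must be > 0", "nibgm_config_error")
  }
  if (cfg$led_phase_s <= 0) {
    stop_nibgm("led_phase_s must be > 0", "nibgm_config_error")
  }
  if (length(cfg$glucose_range) != 2L ||
      cfg$glucose_range[1] >= cfg$glucose_range[2]) {
    stop_nibgm("glucose_range must be (lo, hi) with lo < hi",
               "nibgm_config_error")
  }
  for (nm in c("baseline_attenuation", "glucose_coefficient")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(3L, 3L))) {
      stop_nibgm(sprintf("%s must be a 3x3 matrix (wavelength x path)", nm),
                 "nibgm_config_error")
    }
  }
  kap <- cfg$glucose_coefficient
  if (any(kap[, "far"] <= kap[, "near"]) ||
      any(kap[, "trans"] <= kap[, "near"])) {
    stop_nibgm(paste("glucose_coefficient must give positive differential",
                     "slopes (far > near and trans > near per wavelength)"),
               "nibgm_config_error")
  }
  att <- cfg$baseline_attenuation
  if (any(att[, "near"] >= att[, "far"]) || any(att[, "far"] >= att[, "trans"])) {
    stop_nibgm("baseline_attenuation must increase near -> far -> trans",
               "nibgm_config_error")
  }
  invisible(cfg)
}

#' Planted differential absorbances of a synthetic record
#'
#' Closed-form value of the six differential absorbances the simulator plants
#' in a DC record at a given glucose level: for each wavelength,
#' `dA = (A0_path - A0_near) + (kappa_path - kappa_near) * g (+ drift terms)`.
#' The incident intensity cancels exactly, as it does in the measurement
#' model. Used by the generator itself and by recovery checks.
#'
#' @param config A [synth_config()].
#' @param glucose Glucose level, mmol/L.
#' @param drift Optional 3x3 matrix of per-(wavelength, path) absorbance
#'   offsets (rows 625/850/940, columns near/far/trans); defaults to zero.
#' @return Named numeric vector of length 6 in the fixed feature order.
#' @export
planted_absorbances <- function(config, glucose, drift = NULL) {
  att <- config$baseline_attenuation
  kap <- config$glucose_coefficient
  a_tot <- att + kap * glucose
  if (!is.null(drift)) a_tot <- a_tot + drift
  out <- numeric(6)
  for (w in seq_along(WAVELENGTHS)) {
    out[2 * w - 1] <- a_tot[w, "far"] - a_tot[w, "near"]
    out[2 * w] <- a_tot[w, "trans"] - a_tot[w, "near"]
  }
  names(out) <- ABSORBANCE_NAMES
  out
}

#' Planted heart rate at a glucose level
#'
#' Deterministic part of the simulator's HR-glucose coupling, clipped to the
#' physiologic band 45-180 bpm.
#'
#' @inheritParams planted_absorbances
#' @return Heart rate in bpm.
#' @export
planted_heart_rate <- function(config, glucose) {
  hr <- config$heart_rate_baseline + config$hr_glucose_slope * glucose
  min(max(hr, 45), 180)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic acquisition configuration\n")
  cat(sprintf("  wavelengths: %s nm; paths: %s\n",
              paste(WAVELENGTHS, collapse = "/"), paste(PATHS, collapse = "/")))
  cat(sprintf("  sampling: %g Hz, %g s per LED phase\n",
              x$sampling_rate, x$led_phase_s))
  cat(sprintf("  glucose range: %.1f-%.1f mmol/L (baseline %.1f)\n",
              x$glucose_range[1], x$glucose_range[2], x$glucose_baseline))
  cat(sprintf("  HR coupling: %.0f %+.1f bpm per mmol/L\n",
              x$heart_rate_baseline, x$hr_glucose_slope))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
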