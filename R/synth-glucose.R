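#' Deterministic daily glucose profile
#'
#' Closed-form noise-free component of the simulated glucose trajectory:
#' subject baseline plus one gamma-density-shaped postprandial excursion per
#' meal. Each excursion is normalised to peak exactly at
#' `config$excursion_mmol` one hour after the meal (gamma shape 3, scale
#' 0.5 h), qualitatively matching sampling before meals and during the two
#' hours after them.
#'
#' @param config A [synth_config()].
#' @param t_h Time of day in hours (vectorised).
#' @param baseline Subject baseline, mmol/L; defaults to
#'   `config$glucose_baseline`.
#' @return Glucose in mmol/L, not yet clipped to `config$glucose_range`.
#' @export
glucose_profile <- function(config, t_h, baseline = config$glucose_baseline) {
  shape <- 3
  scale <- 0.5
  peak <- dgamma((shape - 1) * scale, shape = shape, scale = scale)
  g <- rep(baseline, length(t_h))
  for (m in config$meal_times_h) {
    dt <- t_h - m
    pos <- dt > 0
    if (any(pos)) {
      g[pos] <- g[pos] +
        config$excursion_mmol * dgamma(dt[pos], shape = shape, scale = scale) / peak
    }
  }
  g
}

#' Generate a seeded synthetic glucose trajectory
#'
#' Simulates a multi-day reference glucose series: the deterministic profile
#' of [glucose_profile()] plus stationary AR(1) noise, clipped to the
#' configured glucose range. Samples are evenly spaced over the daily
#' sampling window; timestamps are strictly increasing across days.
#'
#' @param config A [synth_config()].
#' @param n_samples_per_day Samples per day (>= 1).
#' @param n_days Number of days (>= 1).
#' @param baseline Subject baseline, mmol/L.
#' @param seed Seed; defaults to `config$seed`.
#' @return A `glucose_series` data frame with columns `time_s`, `day`,
#'   `glucose` (mmol/L).
#' @examples
#' cfg <- synth_config(seed = 7)
#' gs <- generate_glucose_trajectory(cfg, n_samples_per_day = 17, n_days = 2)
#' range(gs$glucose)
#' @export
generate_glucose_trajectory <- function(config, n_samples_per_day, n_days,
                                        baseline = config$glucose_baseline,
                                        seed = config$seed) {
  n_samples_per_day <- check_count(n_samples_per_day, "n_samples_per_day")
  n_days <- check_count(n_days, "n_days")
  validate_synth_config(config)

  withr::with_seed(seed, {
    t_h <- if (n_samples_per_day == 1L) {
      mean(config$day_window_h)
    } else {
      seq(config$day_window_h[1], config$day_window_h[2],
          length.out = n_samples_per_day)
    }
    n <- n_samples_per_day * n_days
    rho <- config$glucose_noise_rho
    innov_sd <- config$glucose_noise_sd * sqrt(1 - rho^2)
    noise <- numeric(n)
    if (config$glucose_noise_sd > 0) {
      noise[1] <- rnorm(1, 0, config$glucose_noise_sd)
      if (n > 1) {
        eps <- rnorm(n - 1, 0, innov_sd)
        for (i in 2:n) noise[i] <- rho * noise[i - 1] + eps[i - 1]
      }
    }
    day <- rep(seq_len(n_days), each = n_samples_per_day)
    tod <- rep(t_h, n_days)
    g <- glucose_profile(config, tod, baseline) + noise
    g <- pmin(pmax(g, config$glucose_range[1]), config$glucose_range[2])
    out <- data.frame(
      time_s = (day - 1) * 86400 + tod * 3600,
      day = day,
      glucose = g
    )
    class(out) <- c("glucose_series", "data.frame")
    out
  })
}
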