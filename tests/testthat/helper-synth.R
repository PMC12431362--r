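# Shared fixtures and independent oracles, built in code at test time.

# A configuration with every stochastic term switched off: DC/AC noise,
# absorbance drift, HR jitter, beat jitter and trajectory noise. Planted
# couplings (attenuation law, HR-glucose slope) remain.
noiseless_config <- function(seed = 1L, ...) {
  args <- list(noise_sd_dc = 0, noise_sd_ac = 0, absorbance_drift_sd = 0,
               hr_jitter_sd = 0, beat_jitter_rel = 0, glucose_noise_sd = 0,
               seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# Independent scalar-loop evaluation of the LSTM cell update: plain for
# loops and running sums, no matrix algebra, kept deliberately separate
# from the vectorised implementation it checks.
lstm_cell_oracle <- function(x, state, params) {
  hh <- length(state$h)
  d <- length(x)
  z <- c(state$h, x)
  gate <- function(block, act) {
    out <- numeric(hh)
    for (r in seq_len(hh)) {
      acc <- params$b[(block - 1) * hh + r]
      for (cc in seq_len(hh + d)) {
        acc <- acc + params$W[(block - 1) * hh + r, cc] * z[cc]
      }
      out[r] <- act(acc)
    }
    out
  }
  f <- gate(1, function(a) 1 / (1 + exp(-a)))
  i <- gate(2, function(a) 1 / (1 + exp(-a)))
  o <- gate(3, function(a) 1 / (1 + exp(-a)))
  g <- gate(4, tanh)
  c_new <- numeric(hh)
  h_new <- numeric(hh)
  for (r in seq_len(hh)) {
    c_new[r] <- f[r] * state$c[r] + i[r] * g[r]
    h_new[r] <- o[r] * tanh(c_new[r])
  }
  list(h = h_new, c = c_new, f = f, i = i, o = o, c_tilde = g)
}

# A clean pulse train for preprocessing tests: Gaussian systolic lobes at a
# fixed beat frequency, optional linear drift, returned as a raw segment.
make_pulse_train <- function(freq_hz = 1.2, dur_s = 15, fs = 200,
                             drift_slope = 0, width_s = 0.08) {
  tt <- seq(0, dur_s, by = 1 / fs)
  x <- drift_slope * tt
  beats <- seq(0.4, dur_s - 0.4, by = 1 / freq_hz)
  for (b in beats) x <- x + exp(-((tt - b)^2) / (2 * width_s^2))
  ppg_segment(x, fs, "raw")
}

# Closed polygons of the type-1 consensus grid zones (B-E; everything else
# is A), assembled from the exported boundary vertices. Used with an
# independent point-in-polygon routine as the dual-route oracle.
parkes_type1_polygons <- function() {
  v <- parkes_grid("type1")
  up <- v$upper
  lo <- v$lower
  poly <- function(...) {
    m <- rbind(...)
    list(x = m[, 1], y = m[, 2])
  }
  rev_m <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(
    E = poly(up$de, c(0, 550)),
    D_up = poly(up$cd, c(50, 550), rev_m(up$de)),
    D_lo = poly(lo$cd, c(550, 0)),
    C_up = poly(up$bc, c(125, 550), rev_m(up$cd)),
    C_lo = poly(lo$bc, c(550, 150), rev_m(lo$cd)),
    B_up = poly(up$ab, c(260, 550), rev_m(up$bc)),
    B_lo = poly(lo$ab, c(550, 250), rev_m(lo$bc))
  )
}

# Oracle zone assignment in mg/dL via pracma::inpolygon over the closed
# zone polygons, most severe zone first.
parkes_zone_oracle <- function(x_mgdl, y_mgdl) {
  polys <- parkes_type1_polygons()
  sev <- c("E", "D_up", "D_lo", "C_up", "C_lo", "B_up", "B_lo")
  out <- rep("A", length(x_mgdl))
  for (k in sev) {
    hit <- out == "A" &
      pracma::inpolygon(x_mgdl, y_mgdl, polys[[k]]$x, polys[[k]]$y)
    out[hit] <- substr(k, 1, 1)
  }
  out
}

# Small day-grouped study reused by the model-level tests.
small_study_features <- function(seed = 5L, n_subjects = 2, n_days = 2,
                                 samples_per_day = 9) {
  st <- generate_study(synth_config(seed = seed), n_subjects, n_days,
                       samples_per_day)
  study_features(st)
}
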