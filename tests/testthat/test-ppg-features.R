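test_that("the zero-phase Butterworth filter has the designed passband", {
  fs <- 200
  tt <- seq(0, 20, by = 1 / fs)
  interior <- 1000:3000  # avoid edge transients when measuring amplitude

  seg2 <- ppg_segment(sin(2 * pi * 2 * tt), fs, "raw")
  out2 <- lowpass_filter(seg2)
  expect_equal(max(abs(out2$samples[interior])), 1, tolerance = 0.01)

  seg40 <- ppg_segment(sin(2 * pi * 40 * tt), fs, "raw")
  out40 <- lowpass_filter(seg40)
  expect_lt(max(abs(out40$samples[interior])), 0.05)

  segc <- ppg_segment(rep(2.5, 400), fs, "raw")
  expect_equal(lowpass_filter(segc)$samples, rep(2.5, 400), tolerance = 1e-6)

  expect_error(lowpass_filter(ppg_segment(sin(tt), fs, "raw"), cutoff_hz = 120),
               class = "nibgm_config_error")
  expect_error(lowpass_filter(out2), class = "nibgm_preprocessing_error")
})

test_that("spline detrending removes linear baseline drift", {
  drifted <- lowpass_filter(make_pulse_train(drift_slope = 0.5))
  det <- remove_baseline(drifted)
  x <- det$samples
  peaks <- nibgm:::find_local_peaks(x, 66, 0.3 * diff(range(x)))
  feet <- vapply(seq_len(length(peaks) - 1), function(i) {
    idx <- peaks[i]:peaks[i + 1]
    min(x[idx])
  }, numeric(1))
  amp <- diff(range(x))
  expect_lt(diff(range(feet)), 0.05 * amp)

  # drift-free input: the fitted baseline is near-constant
  flat <- lowpass_filter(make_pulse_train(drift_slope = 0))
  det0 <- remove_baseline(flat)
  baseline <- flat$samples - det0$samples
  expect_lt(max(abs(baseline - mean(baseline))),
            0.02 * diff(range(flat$samples)))

  short <- lowpass_filter(make_pulse_train(freq_hz = 1, dur_s = 2.2))
  expect_error(remove_baseline(short), class = "nibgm_preprocessing_error")
})

test_that("min-max normalization maps to [0, 1] and is idempotent", {
  seg <- ppg_segment(c(3, 9, 5, 7), 200, "detrended")
  norm <- normalize_ppg(seg)
  expect_equal(range(norm$samples), c(0, 1))

  already <- ppg_segment(c(0, 1, 0.4, 0.8), 200, "detrended")
  expect_equal(normalize_ppg(already)$samples, c(0, 1, 0.4, 0.8))

  expect_error(normalize_ppg(ppg_segment(rep(2, 10), 200, "detrended")),
               class = "nibgm_degenerate_error")
})

test_that("systolic peaks of a 1 Hz pulse train are found at 200-sample gaps", {
  raw <- make_pulse_train(freq_hz = 1, dur_s = 10)
  seg <- normalize_ppg(remove_baseline(lowpass_filter(raw)))
  peaks <- detect_peaks(seg)
  expect_true(length(peaks) %in% c(9L, 10L))
  expect_true(all(abs(diff(peaks) - 200) <= 1))

  flat <- ppg_segment(rep(0.5, 2000), 200, "normalized")
  expect_error(detect_peaks(flat), class = "nibgm_feature_error")

  two <- make_pulse_train(freq_hz = 1, dur_s = 2.4)
  two$state <- "normalized"
  expect_length(detect_peaks(two), 2L)
})

test_that("heart-rate features follow the interval arithmetic", {
  expect_equal(heart_rate_features(seq(1, 2001, by = 200), 200),
               c(hr_mu = 60, hr_sigma = 0))

  # intervals of 0.5 s and 1.0 s at 200 Hz: HR series {120, 60};
  # sample standard deviation = |120 - 90| * sqrt(2)
  hr <- heart_rate_features(c(1, 101, 301), 200)
  expect_equal(unname(hr["hr_mu"]), 90)
  expect_equal(unname(hr["hr_sigma"]), 30 * sqrt(2))

  expect_error(heart_rate_features(c(5), 200), class = "nibgm_feature_error")
})

test_that("framing follows the overlap formula and conserves the signal", {
  x <- sin(seq_len(2000) / 7)
  fr <- frame_signal(x, 400, 200)
  expect_equal(dim(fr), c(400L, 9L))
  expect_equal(ncol(frame_signal(x[1:400], 400, 200)), 1L)
  expect_equal(ncol(frame_signal(sin(seq_len(2100) / 7), 400, 200)), 9L)

  # consecutive frames share exactly the overlap
  for (n in 1:8) expect_equal(fr[201:400, n], fr[1:200, n + 1])
  # overlap-aware reassembly reproduces the covered prefix exactly
  rebuilt <- c(fr[1:200, 1:9], fr[201:400, 9])
  expect_identical(rebuilt, x[1:2000])

  expect_error(frame_signal(x[1:399], 400, 200), class = "nibgm_framing_error")
  expect_error(frame_signal(x, 400, 400), class = "nibgm_config_error")
})

test_that("the Teager energy operator matches its closed form and oracle", {
  expect_equal(kte_sequence(rep(3, 50)), rep(0, 48))
  expect_equal(kte_sequence(c(0, 1, 0)), 1)

  tau <- seq_len(400)
  kte <- kte_sequence(sin(0.1 * tau))
  expect_equal(kte, rep(sin(0.1)^2, 398), tolerance = 1e-9)
  expect_lt(diff(range(kte)), 1e-9)

  # independent elementwise brute-force loop, exact agreement
  set.seed(77)
  for (rep_i in 1:50) {
    frame <- rnorm(sample(3:32, 1))
    l <- length(frame)
    brute <- numeric(l - 2)
    for (t in 2:(l - 1)) brute[t - 1] <- frame[t]^2 - frame[t + 1] * frame[t - 1]
    expect_identical(kte_sequence(frame), brute)
  }

  expect_error(kte_sequence(c(1, 2)), class = "nibgm_feature_error")
})

test_that("log-energy is decadic with a guarded zero floor", {
  expect_equal(loge(c(1)), 0, tolerance = 1e-12)
  expect_equal(loge(c(6, 8)), 2, tolerance = 1e-12)  # 36 + 64 = 100
  expect_equal(loge(rep(0, 400)), -12)
  expect_error(loge(numeric(0)), class = "nibgm_feature_error")
})

test_that("extract_features yields the 12-element vector in fixed order", {
  rec <- generate_device_record(5.5, synth_config(seed = 10))
  fv <- extract_features(rec)
  expect_length(fv, 12)
  expect_identical(names(fv),
                   c("hr_mu", "hr_sigma", "kte_mu", "kte_sigma", "loge_mu",
                     "loge_sigma", "da_nf_625", "da_nt_625", "da_nf_850",
                     "da_nt_850", "da_nf_940", "da_nt_940"))
  expect_true(all(is.finite(fv)))

  fv2 <- extract_features(generate_device_record(5.5, synth_config(seed = 10)))
  expect_identical(fv, fv2)
})

test_that("features respond to glucose through the planted couplings", {
  cfg <- noiseless_config()
  f4 <- extract_features(generate_device_record(4, cfg))
  f9 <- extract_features(generate_device_record(9, cfg))
  expect_lt(f9["hr_mu"], f4["hr_mu"])
  expect_true(all(f9[7:12] > f4[7:12]))
})

test_that("HR and shape features are invariant to AC amplitude scaling", {
  rec <- generate_device_record(6, synth_config(seed = 12))
  fv <- extract_features(rec)
  rec_scaled <- rec
  rec_scaled$pd3_ac <- rec$pd3_ac * 7.5
  expect_equal(extract_features(rec_scaled), fv, tolerance = 1e-8)
})
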