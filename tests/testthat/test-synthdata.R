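test_that("glucose trajectories respect the configured range and seed", {
  cfg <- synth_config(seed = 42)
  gs <- generate_glucose_trajectory(cfg, n_samples_per_day = 17, n_days = 4)
  expect_true(all(gs$glucose >= 3.9 & gs$glucose <= 9.3))
  expect_true(all(diff(gs$time_s) > 0))
  expect_equal(nrow(gs), 17 * 4)

  gs2 <- generate_glucose_trajectory(cfg, n_samples_per_day = 17, n_days = 4)
  expect_identical(gs, gs2)

  expect_error(generate_glucose_trajectory(cfg, 0, 1), class = "nibgm_config_error")
  expect_error(synth_config(glucose_range = c(9, 4)),
               class = "nibgm_config_error")
})

test_that("a planted postprandial excursion amplitude is recovered", {
  # single meal, no noise, dense sampling: the day maximum sits on top of
  # the gamma-shaped bump, so max - baseline recovers the amplitude
  cfg <- noiseless_config(meal_times_h = 12, excursion_mmol = 2.0,
                          glucose_range = c(2, 12), glucose_baseline = 5)
  gs <- generate_glucose_trajectory(cfg, n_samples_per_day = 841, n_days = 1)
  expect_equal(max(gs$glucose) - 5, 2.0, tolerance = 0.01)
})

test_that("DC channels order near > far > trans at every stable sample", {
  rec <- generate_device_record(5.5, noiseless_config())
  segs <- extract_stable_segments(rec)
  for (sg in segs) {
    idx <- sg$start:sg$end
    expect_true(all(rec$pd1_dc[idx] > rec$pd2_dc[idx]))
    expect_true(all(rec$pd2_dc[idx] > rec$pd3_dc[idx]))
  }
  expect_error(generate_device_record(-1, noiseless_config()),
               class = "nibgm_domain_error")
})

test_that("a custom planted near-far absorbance is recovered downstream", {
  # choose attenuation/coefficient so dA_nf(850) = 0.264 + 0.006 * 6 = 0.30
  att <- default_baseline_attenuation()
  att["850", "far"] <- att["850", "near"] + 0.264
  cfg <- noiseless_config(baseline_attenuation = att)
  rec <- generate_device_record(6.0, cfg)
  da <- compute_absorbance_set(rec)
  expect_equal(unname(da["da_nf_850"]), 0.30, tolerance = 1e-6)
})

test_that("the beat rate of the generated PPG follows the planted HR coupling", {
  cfg <- noiseless_config()  # baseline 75, slope -2 => 65 bpm at g = 5
  rec <- generate_device_record(5, cfg)
  seg940 <- extract_stable_segments(rec)[["940"]]
  seg <- ppg_segment(rec$pd3_ac[seg940$start:seg940$end], 200, "raw")
  seg <- normalize_ppg(remove_baseline(lowpass_filter(seg)))
  peaks <- detect_peaks(seg)
  hr <- heart_rate_features(peaks, 200)
  expect_equal(unname(hr["hr_mu"]), 65, tolerance = 1)
})

test_that("study layout matches the requested dimensions and is seeded", {
  st <- generate_study(synth_config(seed = 9), 4, 4, 17)
  expect_equal(nrow(st$manifest), 272)
  expect_equal(length(unique(st$manifest$subject_day)), 16)
  expect_equal(length(st$records), 272)

  st1 <- generate_study(synth_config(seed = 3), 1, 1, 1)
  expect_equal(nrow(st1$manifest), 1)

  st_a <- generate_study(synth_config(seed = 8), 2, 1, 3)
  st_b <- generate_study(synth_config(seed = 8), 2, 1, 3)
  expect_identical(st_a$manifest, st_b$manifest)
  expect_identical(st_a$records, st_b$records)
})

test_that("glucose monotonically raises absorbances and lowers heart rate", {
  cfg <- noiseless_config()
  g <- c(4, 6.5, 9)
  da <- sapply(g, function(gi) {
    compute_absorbance_set(generate_device_record(gi, cfg))
  })
  for (r in seq_len(nrow(da))) expect_true(all(diff(da[r, ]) > 0))
  hr <- sapply(g, function(gi) planted_heart_rate(cfg, gi))
  expect_true(all(diff(hr) < 0))
})

test_that("absorbance recovery error scales with the planted drift", {
  err_at <- function(sd) {
    cfg <- noiseless_config(absorbance_drift_sd = sd)
    mean(sapply(1:12, function(s) {
      rec <- generate_device_record(6, cfg, seed = s)
      mean(abs(compute_absorbance_set(rec) - planted_absorbances(cfg, 6)))
    }))
  }
  e1 <- err_at(0.005)
  e2 <- err_at(0.02)
  expect_gt(e2, e1)
  expect_gt(e2 / e1, 2)   # expected ratio 4 for sd ratio 4
  expect_lt(e2 / e1, 8)
})
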