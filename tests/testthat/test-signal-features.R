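test_that("R-peak detection recovers clean beat trains to within one sample", {
  ecg <- synth_ecg(60, duration_s = 60, seed = 1)
  truth <- attr(ecg, "beat_times_s")
  b <- detect_r_peaks(ecg)
  expect_equal(length(b$r_peak_times_s), length(truth), tolerance = 0.02)
  matched <- sapply(b$r_peak_times_s, function(t) min(abs(truth - t)))
  expect_lte(max(matched), 1 / ecg$sampling_rate + 1e-9)
  expect_true(all(abs(b$rr_intervals_s - 1) < 0.003))
  expect_true(all(b$rr_valid_mask))
})

test_that("R-R intervals outside 40-180 bpm are masked invalid", {
  # beats at 1 s spacing with one 2 s pause (30 bpm instantaneous)
  times <- c(seq(0, 29, by = 1), seq(31, 59, by = 1))
  ecg <- render_ecg(times, 60)
  b <- detect_r_peaks(ecg)
  rr <- b$rr_intervals_s
  expect_false(b$rr_valid_mask[which.max(rr)])
  expect_equal(max(rr), 2, tolerance = 0.01)
  expect_true(all(b$rr_valid_mask[rr < 1.5]))
})

test_that("degenerate ECG inputs raise undetectable rhythm", {
  flat <- channel_signal("ecg", rep(0.5, 30 * 500), 500)
  expect_error(detect_r_peaks(flat), "undetectable rhythm")
  nas <- channel_signal("ecg", rep(NA_real_, 30 * 500), 500)
  expect_error(detect_r_peaks(nas), "undetectable rhythm")
})

test_that("mean heart rate matches closed forms", {
  expect_equal(mean_heart_rate(make_beats(rep(0.75, 20)), c(0, 20)), 80)
  expect_equal(mean_heart_rate(make_beats(rep(c(1, 0.5), 10)), c(0, 20)), 80)
  # all intervals masked (30 bpm) -> missing
  slow <- make_beats(rep(2, 10))
  expect_true(suppressMessages(is.na(mean_heart_rate(slow, c(0, 20)))))
})

test_that("SDNN matches hand arithmetic and the population convention", {
  expect_equal(as.numeric(suppressWarnings(
    sdnn(make_beats(rep(0.8, 100)), c(0, 81)))), 0)
  expect_equal(as.numeric(suppressWarnings(
    sdnn(make_beats(rep(c(0.8, 1.0), 50)), c(0, 91)))), 100)
  expect_equal(as.numeric(suppressWarnings(
    sdnn(make_beats(rep(c(0.95, 1.05), 50)), c(0, 101)))), 50)
  # agreement with the brute-force oracle on irregular intervals
  rr <- round(runif(200, 0.7, 1.1), 3)
  expect_equal(as.numeric(suppressWarnings(sdnn(make_beats(rr), c(0, 250)))),
               brute_sdnn_ms(rr))
})

test_that("SDNN is scale-equivariant in the deviations", {
  dev <- rnorm(300, 0, 0.03)
  rr1 <- 0.9 + dev
  rr2 <- 0.9 + 2.5 * dev
  s1 <- as.numeric(suppressWarnings(sdnn(make_beats(rr1), c(0, 400))))
  s2 <- as.numeric(suppressWarnings(sdnn(make_beats(rr2), c(0, 400))))
  expect_equal(s2, 2.5 * s1, tolerance = 1e-10)
  expect_warning(sdnn(make_beats(rr1[1:50]), c(0, 50)), "shorter")
})

test_that("HRV band powers separate single-tone tachograms", {
  # RR modulated only at 0.1 Hz -> LF dominates
  rr_lf <- 0.85 + 0.05 * sin(2 * pi * 0.1 * cumsum(rep(0.85, 400)))
  sp <- hrv_spectrum(make_beats(rr_lf), c(0, 360))
  expect_gt(sp$lf_hf_ratio, 10)
  expect_gt(sp$lf_power / (sp$lf_power + sp$hf_power), 0.9)
  # 0.3 Hz -> HF dominates
  rr_hf <- 0.85 + 0.05 * sin(2 * pi * 0.3 * cumsum(rep(0.85, 400)))
  sp2 <- hrv_spectrum(make_beats(rr_hf), c(0, 360))
  expect_lt(sp2$lf_hf_ratio, 0.1)
  expect_gt(sp2$hf_power / (sp2$lf_power + sp2$hf_power), 0.9)
  # constant tachogram -> negligible power in both bands
  sp3 <- hrv_spectrum(make_beats(rep(0.8, 400)), c(0, 320))
  expect_lt(sp3$lf_power, 1e-6)
  expect_lt(sp3$hf_power, 1e-6)
  # short windows refuse to estimate
  expect_true(is.na(suppressMessages(
    hrv_spectrum(make_beats(rep(0.8, 50)), c(0, 40))$lf_power)))
})

test_that("respiratory cycle detection recovers breathing rate", {
  r1 <- synth_respiration(15, duration_s = 120, seed = 3)
  cy <- respiratory_cycles(r1, c(0, 120))
  expect_equal(cy$rate_breaths_per_min, 15, tolerance = 0.1)
  r2 <- synth_respiration(12, duration_s = 60, seed = 4)
  expect_equal(respiratory_cycles(r2, c(0, 60))$rate_breaths_per_min, 12,
               tolerance = 0.15)
  dc <- channel_signal("respiration", rep(1, 60 * 500), 500)
  expect_true(suppressMessages(!inherits(respiratory_cycles(dc, c(0, 60)),
                                         "resp_cycle_series")))
})

test_that("peak-valley RSA behaves per the cycle rules", {
  # constant RR within every cycle -> 0
  beats <- make_beats(rep(0.8, 200))
  cycles <- make_cycles(seq(0, 160, by = 4))
  expect_equal(rsa_peak_valley(beats, cycles), 0)
  # cycles holding single beats -> missing
  sparse <- make_cycles(seq(0, 60, by = 1.2))
  slow_beats <- make_beats(rep(1.45, 40))
  expect_true(suppressMessages(is.na(rsa_peak_valley(slow_beats, sparse))))
  # synthetic modulation of 6 bpm peak-to-peak recovered within 1 bpm
  ecg <- synth_ecg(75, duration_s = 300, rsa_amplitude_bpm = 6,
                   resp_rate_bpm = 15, seed = 5)
  resp <- synth_respiration(15, duration_s = 300, seed = 6)
  rsa <- rsa_peak_valley(detect_r_peaks(ecg),
                         respiratory_cycles(resp, c(0, 300)))
  expect_equal(rsa, 6, tolerance = 1 / 6)
})

test_that("EDR detection applies threshold, hysteresis and drift immunity", {
  # sub-threshold phasic activity yields no events
  tiny <- synth_eda(4, 5, duration_s = 300, scr_amplitude_us = 0.01,
                    drift_us = 0, seed = 7)
  expect_equal(detect_edr(tiny, c(0, 300))$rate_per_min, 0)
  # detectable train is counted, and tonic drift does not change the count
  eda <- synth_eda(4, 5, duration_s = 600, scr_amplitude_us = 0.3,
                   drift_us = 0, seed = 8)
  n0 <- length(detect_edr(eda, c(0, 600))$event_times_s)
  drifted <- eda
  t <- (seq_along(eda$samples) - 1) / eda$sampling_rate
  drifted$samples <- eda$samples + 1.5 * sin(2 * pi * 0.01 * t)
  expect_equal(length(detect_edr(drifted, c(0, 600))$event_times_s), n0)
  # flat signal warns and reports zero rate with the SCL still computed
  flat <- channel_signal("eda", rep(3, 120 * 500), 500)
  expect_warning(ed <- detect_edr(flat, c(0, 120)), "flat")
  expect_equal(ed$rate_per_min, 0)
  expect_equal(ed$scl_tonic_us, 3, tolerance = 1e-6)
})

test_that("EMG RMS matches closed forms and the brute-force oracle", {
  const <- channel_signal("emg", rep(-0.4, 10 * 500), 500)
  expect_equal(emg_rms(const, c(0, 10)), 0.4)
  noise <- synth_emg(0.1, duration_s = 60, seed = 9)
  expect_equal(emg_rms(noise, c(0, 60)), 0.1, tolerance = 0.01)
  tt <- (0:(10 * 500 - 1)) / 500
  sine <- channel_signal("emg", sin(2 * pi * 50 * tt), 500)
  expect_equal(emg_rms(sine, c(0, 10)), 1 / sqrt(2), tolerance = 0.01)
  x <- rnorm(3000, 0, 0.2)
  ch <- channel_signal("emg", x, 500)
  expect_equal(emg_rms(ch, c(0, 6)), brute_block_rms(x, 100))
})

test_that("feature extraction summarizes every annotated phase", {
  rec <- make_two_phase_recording(seed = 21)
  ft <- suppressMessages(extract_features(rec))
  expect_equal(nrow(ft), 2)
  expect_equal(ft$phase, c("baseline", "tsst"))
  expect_equal(ft$hr_bpm, c(70, 85), tolerance = 1 / 70)
  expect_true(all(is.finite(ft$scl_us)))
  # without EDA, electrodermal features are missing but the rest survive
  rec2 <- rec
  rec2$channels$eda <- NULL
  ft2 <- suppressMessages(extract_features(rec2))
  expect_true(all(is.na(ft2$scl_us)))
  expect_true(all(is.na(ft2$edr_per_min)))
  expect_true(all(is.finite(ft2$hr_bpm)))
})
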