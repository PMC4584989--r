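test_that("channel and recording constructors enforce their invariants", {
  expect_error(channel_signal("ecg", rnorm(10), 500), "at least 2 s")
  expect_error(channel_signal("ecg", rnorm(2000), -1), "positive")
  ch <- channel_signal("eda", runif(2000, 2, 8), 500)
  expect_equal(ch$unit, "uS")

  ph <- phase_annotation(c("baseline", "tsst"), c(0, 300), c(300, 600))
  ecg <- channel_signal("ecg", rnorm(600 * 100), 100)
  eda <- channel_signal("eda", runif(600 * 100), 100)
  expect_s3_class(recording("s1", "experimental", list(ecg, eda), ph),
                  "recording")
  # unequal channel lengths
  short <- channel_signal("eda", runif(500 * 100), 100)
  expect_error(recording("s1", "experimental", list(ecg, short), ph),
               "equal length")
  # mixed sampling rates
  other <- channel_signal("eda", runif(600 * 50), 50)
  expect_error(recording("s1", "experimental", list(ecg, other), ph),
               "sampling_rate")
  # phase outside signal duration
  ph_long <- phase_annotation(c("baseline", "tsst"), c(0, 300), c(300, 700))
  expect_error(recording("s1", "experimental", list(ecg, eda), ph_long),
               "invalid manifest")
})

test_that("phase manifests reject inverted and overlapping intervals", {
  expect_error(phase_annotation("tsst", 300, 200), "invalid manifest")
  expect_error(phase_annotation(c("baseline", "tsst"), c(0, 200), c(300, 500)),
               "overlapping")
  expect_error(phase_annotation("warmup", 0, 10), "unknown phase")
  ph <- phase_annotation(c("tsst", "baseline"), c(300, 0), c(600, 300))
  expect_equal(ph$phase, c("baseline", "tsst"))  # sorted by start
})

test_that("sessions round-trip through the text container", {
  ph <- phase_annotation(c("baseline", "tsst", "scenario1"),
                         c(0, 300, 600), c(300, 600, 720))
  fs <- 100
  chans <- list(
    channel_signal("ecg", rnorm(720 * fs), fs),
    channel_signal("eda", runif(720 * fs, 2, 8), fs),
    channel_signal("respiration", sin(2 * pi * 0.25 * (1:(720 * fs)) / fs), fs),
    channel_signal("emg", rnorm(720 * fs, 0, 0.05), fs))
  rec <- recording("s42", "control", chans, ph)
  profile <- baseline_profile("s42", 0.41, 33, cortisol_final = 0.13)
  missions <- mission_log("s42", 1:2, c(500, 650), 5, c(5, 3), c(0, 2),
                          c(0, 0), 600)
  d1 <- withr::local_tempdir()
  write_session(list(recording = rec, profile = profile, missions = missions),
                d1)
  s2 <- read_session(d1)
  # numeric round trip at declared 1e-6 precision
  expect_equal(s2$recording$channels$ecg$samples, rec$channels$ecg$samples,
               tolerance = 1e-6)
  expect_equal(s2$recording$phases, rec$phases)
  expect_equal(s2$recording$group, "control")
  expect_equal(s2$profile$cortisol_baseline, 0.41)
  expect_equal(s2$missions$objectives_met, c(5L, 3L))
  # write(read(x)) is byte-identical for canonical files
  d2 <- withr::local_tempdir()
  write_session(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = paste("file", f))
  }
})

test_that("missing channels follow the EDA-loss policy", {
  ph <- phase_annotation(c("baseline", "tsst"), c(0, 300), c(300, 600))
  fs <- 100
  chans <- list(channel_signal("ecg", rnorm(600 * fs), fs),
                channel_signal("eda", runif(600 * fs), fs),
                channel_signal("respiration", rnorm(600 * fs), fs),
                channel_signal("emg", rnorm(600 * fs), fs))
  rec <- recording("s1", "experimental", chans, ph)
  d <- withr::local_tempdir()
  write_session(rec, d)
  file.remove(file.path(d, "eda.csv"))
  expect_error(read_session(d), "incomplete session")
  s <- read_session(d, allow_missing = "eda")
  expect_null(s$recording$channels$eda)
  expect_s3_class(s$recording$channels$ecg, "channel_signal")
  file.remove(file.path(d, "ecg.csv"))
  expect_error(read_session(d, allow_missing = "eda"), "incomplete session")
})

test_that("session writing flags degenerate inputs", {
  ph <- phase_annotation("tsst", 0, 600)
  fs <- 100
  rec <- suppressWarnings(recording(
    "s1", "control", list(channel_signal("ecg", rnorm(600 * fs), fs)), ph))
  expect_warning(write_session(rec, withr::local_tempdir()), "baseline")
  rec$channels <- list()
  expect_error(write_session(rec, withr::local_tempdir()), "empty channel set")
})

test_that("baseline profiles validate the STAI contract", {
  expect_error(baseline_profile("s", -0.1, 30), "cortisol")
  expect_error(baseline_profile("s", 0.4, 10), "20, 80")
  items <- c(rep(2L, 10), rep(1L, 10))  # totals 30
  p <- baseline_profile("s", 0.4, 30, stai_items = items)
  expect_equal(p$stai_item_01, 2L)
  expect_error(baseline_profile("s", 0.4, 40, stai_items = items), "total")
})

test_that("mission logs validate counts", {
  expect_error(mission_log("s", 6, 100, 5, 3, 0, 0, 600), "1-5")
  expect_error(mission_log("s", 1, 100, 5, 6, 0, 0, 600), "objectives")
  expect_error(mission_log("s", 1, 100, 5, 3, -1, 0, 600), ">= 0")
})
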