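test_that("STAI scoring reverses keyed items and sums", {
  expect_equal(score_stai(rep(c(1L, 4L), 10)), 50)
  # reverse keying maps x -> 5 - x on the named indices only
  items <- rep(1L, 20)
  expect_equal(score_stai(items, reverse_keyed = 1:10), 10 * 4 + 10 * 1)
  expect_error(score_stai(rep(1L, 19)), "20")
  expect_error(score_stai(c(rep(1L, 19), 5L)), "1-4")
  expect_error(score_stai(c(rep(1L, 19), NA)), "missing")
  # property: equals brute-force summation over random keyed draws
  for (i in 1:25) {
    set.seed(i)
    it <- sample(1:4, 20, replace = TRUE)
    rev_idx <- sample(1:20, sample(0:20, 1))
    brute <- sum(ifelse(seq_len(20) %in% rev_idx, 5 - it, it))
    expect_equal(score_stai(it, rev_idx), brute)
  }
})

test_that("performance score matches the worked example and its bounds", {
  perfect <- mission_log("s", 1, 500, 5, 5, 0, 0, 600)
  expect_equal(performance_score(perfect)$score, 10)
  awful <- mission_log("s", 2, 2400, 5, 0, 20, 3, 600)
  expect_equal(performance_score(awful)$score, 0)
  mid <- mission_log("s", 3, 600, 5, 4, 2, 0, 600)
  expect_equal(performance_score(mid)$score, 7)  # 8 - 2*0.5
  expect_error(performance_score(mission_log("s", 1, 100, 0, 0, 0, 0, 600)),
               "objectives_total")
})

test_that("performance score is monotone in each penalty and in objectives", {
  base <- function(shots = 1, civ = 0, dur = 500, met = 3)
    performance_score(mission_log("s", 1, dur, 5, met, shots, civ, 600))$score
  for (i in 1:20) {
    set.seed(i)
    shots <- sample(0:5, 2); civ <- sample(0:2, 2)
    dur <- sort(runif(2, 300, 1500)); met <- sort(sample(0:5, 2))
    expect_lte(base(shots = max(shots)), base(shots = min(shots)))
    expect_lte(base(civ = max(civ)), base(civ = min(civ)))
    expect_lte(base(dur = dur[2]), base(dur = dur[1]))
    expect_gte(base(met = met[2]), base(met = met[1]))
  }
})

test_that("stress score normalizes by control means", {
  phases <- c("baseline", "tsst", "scenario1")
  cm <- data.frame(phase = phases, hr_mean = c(70, 80, 75),
                   scl_mean = c(5, 6, 5.5))
  # a subject identical to the control means scores 1.0 everywhere
  f <- data.frame(subject_id = "a", group = "experimental", phase = phases,
                  hr_bpm = c(70, 80, 75), scl_us = c(5, 6, 5.5))
  tr <- stress_score(f, cm)
  expect_equal(unname(tr$score_by_phase), c(1, 1, 1))
  expect_equal(tr$pct_change_tsst, 0)
  expect_equal(tr$pct_change_scenarios, 0)
  # HR ratio 1.2 and SCL ratio 1.0 at tsst, baseline at 1.0 -> 1.1, +10%
  f2 <- data.frame(subject_id = "b", group = "experimental", phase = phases,
                   hr_bpm = c(70, 80 * 1.2, 75), scl_us = c(5, 6, 5.5))
  tr2 <- stress_score(f2, cm)
  expect_equal(unname(tr2$score_by_phase[["tsst"]]), 1.1)
  expect_equal(tr2$pct_change_tsst, 10)
  # degenerate control means refuse to normalize
  cm_bad <- cm; cm_bad$scl_mean[1] <- 0
  expect_error(stress_score(f, cm_bad), "strictly positive")
  # missing SCL excludes the subject from trend analysis
  f3 <- f; f3$scl_us[2] <- NA
  expect_error(stress_score(f3, cm), class = "stressres_missing_scl")
})

test_that("trend rules label the worked cases and ignore rescaling", {
  sc <- function(base, tsst, scen)
    setNames(c(base, tsst, scen), c("baseline", "tsst", "scenario1"))
  expect_equal(classify_trend(make_trajectory(sc(1, 1.04, 1.04))), "resistant")
  expect_equal(classify_trend(make_trajectory(sc(1, 1.20, 1.02))), "resilient")
  expect_equal(classify_trend(make_trajectory(sc(1, 1.20, 1.12))), "recovery")
  expect_equal(classify_trend(make_trajectory(sc(1, 1.20, 1.30))),
               "dysfunctional")
  # scale invariance: multiplying all scores by c > 0 keeps the label
  for (i in 1:30) {
    set.seed(i)
    v <- sc(runif(1, 0.5, 2), runif(1, 0.5, 2.5), runif(1, 0.5, 2.5))
    cfac <- runif(1, 0.1, 10)
    expect_equal(classify_trend(make_trajectory(v)),
                 classify_trend(make_trajectory(v * cfac)))
  }
})

test_that("every complete trajectory receives exactly one of the four labels", {
  for (i in 1:100) {
    set.seed(i)
    v <- setNames(runif(4, 0.4, 2.5),
                  c("baseline", "tsst", "scenario1", "scenario2"))
    thr <- runif(1, 0.5, 60)
    lab <- classify_trend(make_trajectory(v), threshold_pct = thr)
    expect_true(lab %in% c("resistant", "resilient", "recovery",
                           "dysfunctional"))
    expect_length(lab, 1)
  }
})

test_that("raising the TSST change through the threshold never restores resistant", {
  sc <- function(t) setNames(c(1, t, 1.2), c("baseline", "tsst", "scenario1"))
  labels <- sapply(seq(1.0, 1.4, by = 0.01),
                   function(t) classify_trend(make_trajectory(sc(t))))
  first_non <- which(labels != "resistant")[1]
  expect_true(all(labels[seq_len(first_non - 1)] == "resistant"))
  expect_true(all(labels[first_non:length(labels)] != "resistant"))
})

test_that("cohort labeling uses experimental subjects only", {
  phases <- c("baseline", "tsst", "scenario1")
  mk <- function(id, group, hr, scl)
    data.frame(subject_id = id, group = group, phase = phases,
               hr_bpm = hr, scl_us = scl)
  features <- rbind(
    mk("c1", "control", c(70, 70, 70), c(5, 5, 5)),
    mk("c2", "control", c(74, 74, 74), c(5.4, 5.4, 5.4)),
    mk("e1", "experimental", c(70, 95, 72), c(5, 7, 5.1)),
    mk("e2", "experimental", c(70, 71, 70), c(5, 5.05, 5)))
  out <- suppressMessages(label_cohort(features))
  expect_equal(sort(out$labels$subject_id), c("e1", "e2"))
  expect_equal(out$labels$label[out$labels$subject_id == "e1"], "resilient")
  expect_equal(out$labels$label[out$labels$subject_id == "e2"], "resistant")
  # control-only cohorts emit no labels
  ctrl_only <- features[features$group == "control", ]
  expect_equal(nrow(suppressMessages(label_cohort(ctrl_only))$labels), 0)
  # a subject with missing SCL is excluded and reported
  features$scl_us[features$subject_id == "e1"] <- NA
  out2 <- suppressMessages(label_cohort(features))
  expect_false("e1" %in% out2$labels$subject_id)
  expect_true("e1" %in% out2$excluded$subject_id)
})
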