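test_that("cohort configuration validates its proportions", {
  expect_error(cohort_config(phenotype_mix = c(resilient = 0.5,
                                               recovery = 0.2)), "sum to 1")
  expect_error(cohort_config(phenotype_mix = c(odd = 1)), "named")
  expect_error(cohort_config(n_control = -1), "non-negative")
  cfg <- cohort_config()
  expect_equal(cfg$n_control + cfg$n_experimental, 39L)
})

test_that("generation is fully deterministic under the seed", {
  cfg <- cohort_config(n_control = 2, n_experimental = 2, baseline_s = 300,
                       tsst_s = 120, scenario_s = 60, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 0)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("file", f))
  # a different seed changes signals but not the schema
  cfg2 <- cohort_config(n_control = 2, n_experimental = 2, baseline_s = 300,
                        tsst_s = 120, scenario_s = 60, seed = 78)
  d3 <- withr::local_tempdir()
  generate_cohort(cfg2, out_dir = d3)
  expect_identical(sort(list.files(d3, recursive = TRUE)), sort(files))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "S01/ecg.csv"))),
                         unname(tools::md5sum(file.path(d3, "S01/ecg.csv")))))
})

test_that("ground-truth phenotype counts come from the seeded mixture draw", {
  cfg <- cohort_config(seed = 31)
  plan <- stressres:::cohort_plan(cfg)
  expect_equal(nrow(plan), 39)
  expect_equal(sum(plan$group == "control"), 20)
  expect_equal(sum(plan$group == "experimental"), 19)
  drawn <- plan$phenotype[plan$group == "experimental"]
  expect_true(all(drawn %in% names(cfg$phenotype_mix)))
  expected <- with_seed_draw <- {
    set.seed(31)
    sample(names(cfg$phenotype_mix), 19, replace = TRUE,
           prob = cfg$phenotype_mix)
  }
  expect_equal(drawn, expected)
  expect_true(all(is.na(plan$phenotype[plan$group == "control"])))
})

test_that("baseline-profile mixture approximates the cohort moments", {
  co <- synth_baseline_cohort(1000, cohort_config(seed = 42))
  expect_equal(mean(co$cortisol_baseline), 0.38, tolerance = 0.05 / 0.38)
  expect_equal(sd(co$cortisol_baseline), 0.28, tolerance = 0.05 / 0.28)
  expect_true(all(co$stai_baseline >= 20 & co$stai_baseline <= 80))
  expect_equal(mean(co$stai_baseline), 30, tolerance = 0.1)
})

test_that("phenotype gradient: resistant high cortisol / low STAI", {
  co <- synth_baseline_cohort(600, cohort_config(seed = 13))
  draws <- t(sapply(1:500, function(i) {
    p <- synth_baseline_profile("resistant", seed = i)
    c(p$cortisol_baseline, p$stai_baseline)
  }))
  expect_gt(median(draws[, 1]), median(co$cortisol_baseline))
  expect_lt(median(draws[, 2]), median(co$stai_baseline))
  rec <- t(sapply(1:500, function(i) {
    p <- synth_baseline_profile("recovery", seed = i)
    c(p$cortisol_baseline, p$stai_baseline)
  }))
  expect_lt(median(rec[, 1]), median(co$cortisol_baseline))
  expect_gt(median(rec[, 2]), median(co$stai_baseline))
})

test_that("phenotype specs stay consistent with the trend rules", {
  sp <- phenotype_specs()
  expect_lte(sp$hr_reactivity_pct[sp$label == "resistant"], 5)
  expect_lte(sp$hr_residual_pct[sp$label == "resilient"], 5)
  expect_gt(sp$hr_residual_pct[sp$label == "recovery"], 5)
  expect_gt(sp$hr_residual_pct[sp$label == "dysfunctional"],
            sp$hr_reactivity_pct[sp$label == "dysfunctional"])
})

test_that("synthetic EDA honors its tonic and event contracts", {
  quiet <- synth_eda(4, 0, duration_s = 300, drift_us = 0, seed = 3)
  # a drift-free, event-free trace is constant, so the flat-signal warning
  # is the expected path here
  ed <- suppressWarnings(detect_edr(quiet, c(0, 300)))
  expect_equal(length(ed$event_times_s), 0)
  expect_equal(ed$scl_tonic_us, 4, tolerance = 0.05 / 4)
  train <- synth_eda(4, 5, duration_s = 600, drift_us = 0.05, seed = 4)
  expect_gt(length(attr(train, "scr_times_s")), 0)
})

test_that("experimental cohorts sit above control at the stressor", {
  cfg <- cohort_config(n_control = 4, n_experimental = 4, baseline_s = 300,
                       tsst_s = 300, scenario_s = 60, seed = 21)
  co <- suppressMessages(cohort_features(cfg))
  tsst <- co$features[co$features$phase == "tsst", ]
  cm <- suppressMessages(control_means(co$features))
  score <- function(rows) {
    m <- merge(rows, cm, by = "phase")
    mean(0.5 * (m$hr_bpm / m$hr_mean + m$scl_us / m$scl_mean))
  }
  expect_gt(score(tsst[tsst$group == "experimental", ]),
            score(tsst[tsst$group == "control", ]))
})
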