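#' Score the state portion of the STAI
#'
#' Twenty items rated 1-4; anxiety-absent statements are reverse keyed
#' (`x -> 5 - x`) before summation, so totals span 20-80 with higher values
#' indicating more perceived stress. Item responses produced by this
#' package's generator are already keyed, so the default reverse set is
#' empty.
#'
#' @param items integer vector of 20 responses, each in 1-4.
#' @param reverse_keyed indices (in 1..20) of reverse-keyed items.
#' @return the total score, an integer in `[20, 80]`.
#' @export
#' @examples
#' score_stai(rep(1, 20))   # 20
#' score_stai(rep(4, 20))   # 80
score_stai <- function(items, reverse_keyed = integer(0)) {
  if (length(items) != 20L || anyNA(items))
    sr_stop("STAI requires 20 non-missing item responses")
  items <- as.integer(items)
  if (any(items < 1L | items > 4L))
    sr_stop("STAI item responses must lie in 1-4")
  if (length(reverse_keyed)) {
    if (any(!reverse_keyed %in% 1:20)) sr_stop("reverse_keyed must index 1..20")
    items[reverse_keyed] <- 5L - items[reverse_keyed]
  }
  sum(items)
}

#' Mission performance score
#'
#' Summarizes a mission log into a 0-10 score rewarding objective completion
#' and penalizing shots received, civilian hits and time over the scenario
#' budget:
#' `clamp(10 * met/total - w_shot*shots - w_civ*civilian_hits -
#' w_time*max(0, duration/par - 1), 0, 10)`.
#' Default weights `w_shot = 0.5`, `w_civ = 2`, `w_time = 2` are exposed in
#' [analysis_config()].
#'
#' @param log a one-row [mission_log()] (or a multi-row log: one score per
#'   row).
#' @param config an [analysis_config()].
#' @return a `data.frame` with columns `subject_id`, `scenario`, `score`.
#' @export
#' @examples
#' log <- mission_log("s1", 1, 500, 5, 4, 2, 0, 600)
#' performance_score(log)$score  # 8 - 1 = 7
performance_score <- function(log, config = analysis_config()) {
  stopifnot(inherits(log, "mission_log") || is.data.frame(log))
  if (any(log$objectives_total == 0L))
    sr_stop("objectives_total must be positive")
  raw <- 10 * log$objectives_met / log$objectives_total -
    config$performance.w_shot * log$times_shot -
    config$performance.w_civ * log$civilian_hits -
    config$performance.w_time * pmax(0, log$duration_s / log$par_time_s - 1)
  data.frame(subject_id = log$subject_id, scenario = log$scenario,
             score = pmin(10, pmax(0, raw)), stringsAsFactors = FALSE)
}

#' Per-phase control-group means of heart rate and SCL
#'
#' @param features a multi-subject feature table ([extract_features()] rows
#'   bound together) containing control-group subjects.
#' @param normalization `"per_phase"` (one mean per phase) or `"grand"`
#'   (the phase column then repeats the grand control mean).
#' @return `data.frame` with columns `phase`, `hr_mean`, `scl_mean`.
#' @export
control_means <- function(features, normalization = c("per_phase", "grand")) {
  normalization <- match.arg(normalization)
  ctrl <- features[features$group == "control", , drop = FALSE]
  if (nrow(ctrl) == 0L) sr_stop("no control-group rows in feature table")
  if (normalization == "per_phase") {
    agg <- aggregate(cbind(hr_bpm, scl_us) ~ phase, data = ctrl,
                     FUN = mean, na.action = stats::na.omit)
    out <- data.frame(phase = agg$phase, hr_mean = agg$hr_bpm,
                      scl_mean = agg$scl_us, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(phase = unique(ctrl$phase),
                      hr_mean = mean(ctrl$hr_bpm, na.rm = TRUE),
                      scl_mean = mean(ctrl$scl_us, na.rm = TRUE),
                      stringsAsFactors = FALSE)
  }
  if (any(!is.finite(out$hr_mean)) || any(!is.finite(out$scl_mean)) ||
      any(out$hr_mean <= 0) || any(out$scl_mean <= 0))
    sr_stop("control means must be finite and strictly positive")
  out
}

#' Control-normalized physiological stress score
#'
#' For each phase, the subject's heart rate and skin conductance level are
#' divided by the corresponding control-group means and combined as a
#' weighted mean (default equal weights), so a score of 1.0 is
#' control-typical. Percent changes from baseline to the TSST and from
#' baseline to the scenario aggregate summarize the trajectory.
#'
#' @param features feature rows of one subject (all phases).
#' @param ctrl_means a [control_means()] table.
#' @param config an [analysis_config()]; `stress_score.hr_weight` sets the
#'   heart-rate weight, `trend.scenario_aggregate` chooses the scenario
#'   summary (`"mean"`, `"last"` or `"max"`).
#' @return an object of class `stress_trajectory`: list with `subject_id`,
#'   `score_by_phase` (named numeric), `score_scenarios` (the aggregate),
#'   `pct_change_tsst`, `pct_change_scenarios`.
#' @export
stress_score <- function(features, ctrl_means, config = analysis_config()) {
  sid <- unique(features$subject_id)
  if (length(sid) != 1L) sr_stop("stress_score expects a single subject")
  m <- merge(features, ctrl_means, by = "phase", sort = FALSE)
  if (any(m$hr_mean <= 0) || any(m$scl_mean <= 0))
    sr_stop("control means must be strictly positive")
  if (any(!is.finite(m$scl_us)))
    sr_stop("missing SCL: subject excluded from trend analysis",
            "stressres_missing_scl")
  if (any(!is.finite(m$hr_bpm)))
    sr_stop("missing heart rate: subject excluded from trend analysis",
            "stressres_missing_hr")
  w <- config$stress_score.hr_weight
  score <- w * m$hr_bpm / m$hr_mean + (1 - w) * m$scl_us / m$scl_mean
  names(score) <- m$phase
  if (!all(c("baseline", "tsst") %in% names(score)))
    sr_stop("trajectory requires baseline and tsst scores")
  scen <- score[names(score) %in% SCENARIO_PHASES]
  if (length(scen) == 0L) sr_stop("trajectory requires at least one scenario")
  agg <- switch(config$trend.scenario_aggregate,
                mean = mean(scen),
                last = scen[[length(scen)]],
                max = max(scen),
                sr_stop("unknown trend.scenario_aggregate"))
  base <- score[["baseline"]]
  structure(list(subject_id = sid,
                 score_by_phase = score[intersect(PHASES, names(score))],
                 score_scenarios = agg,
                 pct_change_tsst = 100 * (score[["tsst"]] - base) / base,
                 pct_change_scenarios = 100 * (agg - base) / base),
            class = "stress_trajectory")
}

#' @export
print.stress_trajectory <- function(x, ...) {
  cat(sprintf("<stress_trajectory> %s: dTSST %+.1f%%, dScenarios %+.1f%%\n",
              x$subject_id, x$pct_change_tsst, x$pct_change_scenarios))
  print(round(x$score_by_phase, 3))
  invisible(x)
}

#' Rule-based resilience-trend label
#'
#' Applies the percent-change rules to a stress trajectory:
#' * **resistant** - baseline-to-TSST change at most the threshold (default
#'   5%): heart rate and SCL stayed unresponsive to the stressor;
#' * **resilient** - TSST change above threshold but the baseline-to-scenario
#'   change at most threshold: a reaction that returned to baseline;
#' * **recovery** - both changes above threshold, the scenario aggregate
#'   below the TSST score: a reaction with only partial return;
#' * **dysfunctional** - both changes above threshold and the scenario
#'   aggregate above the TSST score: the response kept rising.
#'
#' The label depends only on ratios of phase scores, so it is invariant to
#' positive rescaling of the trajectory.
#'
#' @param traj a [stress_score()] trajectory.
#' @param threshold_pct percent-change threshold (default 5).
#' @return one of `"resistant"`, `"resilient"`, `"recovery"`,
#'   `"dysfunctional"`.
#' @export
classify_trend <- function(traj, threshold_pct = 5) {
  stopifnot(inherits(traj, "stress_trajectory"))
  if (!is.finite(traj$pct_change_tsst) || !is.finite(traj$pct_change_scenarios))
    sr_stop("incomplete trajectory: cannot label")
  if (traj$pct_change_tsst <= threshold_pct) return("resistant")
  if (traj$pct_change_scenarios <= threshold_pct) return("resilient")
  if (traj$score_scenarios > traj$score_by_phase[["tsst"]])
    return("dysfunctional")
  "recovery"
}

#' Label an experimental cohort
#'
#' Computes control means from the control-group rows, stress trajectories
#' for every experimental subject with complete heart-rate and SCL features,
#' and the trend label of each. Subjects with missing SCL (electrodermal
#' sensor loss) or heart rate are excluded from labeling and reported.
#'
#' @param features multi-subject feature table (both groups).
#' @param config an [analysis_config()].
#' @return list with `labels` (`data.frame`: `subject_id`, `label`,
#'   `pct_change_tsst`, `pct_change_scenarios`), `counts` (table over the
#'   four labels), `trajectories` (named list), `excluded` (`data.frame` with
#'   `subject_id`, `reason`), `control_means`.
#' @export
label_cohort <- function(features, config = analysis_config()) {
  cm <- control_means(features, config$stress_score.normalization)
  exp_ids <- unique(features$subject_id[features$group == "experimental"])
  labels <- list(); trajs <- list(); excluded <- list()
  for (sid in exp_ids) {
    f <- features[features$subject_id == sid, , drop = FALSE]
    res <- tryCatch(stress_score(f, cm, config), error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[sid]] <- conditionMessage(res)
      stage_log("scoring", "subject ", sid, " excluded: ",
                conditionMessage(res))
      next
    }
    trajs[[sid]] <- res
    labels[[sid]] <- data.frame(
      subject_id = sid,
      label = classify_trend(res, config$trend.threshold_pct),
      pct_change_tsst = res$pct_change_tsst,
      pct_change_scenarios = res$pct_change_scenarios,
      stringsAsFactors = FALSE)
  }
  lab_df <- if (length(labels)) do.call(rbind, labels) else
    data.frame(subject_id = character(), label = character(),
               pct_change_tsst = numeric(), pct_change_scenarios = numeric(),
               stringsAsFactors = FALSE)
  rownames(lab_df) <- NULL
  counts <- table(factor(lab_df$label, levels = RESILIENCE_LABELS))
  excl_df <- data.frame(subject_id = as.character(names(excluded) %||% character()),
                        reason = as.character(unlist(excluded) %||% character()),
                        stringsAsFactors = FALSE)
  stage_log("scoring", sprintf("labeled %d/%d experimental subjects",
                               nrow(lab_df), length(exp_ids)))
  list(labels = lab_df, counts = counts, trajectories = trajs,
       excluded = excl_df, control_means = cm)
}
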