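#' Cohort-level analysis of a feature table
#'
#' The in-memory core of the pipeline: computes control means, stress
#' trajectories and trend labels for the experimental group, screens
#' baseline-profile outliers among the labeled subjects, and (when at least
#' two classes remain) fits and resubstitution-evaluates the SGD linear
#' classifier on the non-outlier training set.
#'
#' @param features multi-subject feature table.
#' @param profiles `data.frame` of baseline profiles (one row per subject).
#' @param config an [analysis_config()].
#' @param seed integer seed for the classifier's epoch shuffle.
#' @return list with `labels`, `counts`, `trajectories`, `excluded`,
#'   `control_means`, `baseline_set` (labels joined with profiles and
#'   outlier flags), `model` (or `NULL`), `confusion` (or `NULL`).
#' @export
analyze_cohort <- function(features, profiles, config = analysis_config(),
                           seed = 1L) {
  stage_log("analyze", sprintf("feature rows in: %d (%d subjects)",
                               nrow(features), length(unique(features$subject_id))))
  lab <- label_cohort(features, config)
  baseline_set <- merge(lab$labels,
                        profiles[, c("subject_id", "cortisol_baseline",
                                     "stai_baseline")],
                        by = "subject_id")
  model <- NULL; confusion <- NULL
  if (nrow(baseline_set) >= 5L) {
    baseline_set <- flag_outliers(baseline_set, config$outlier.z_cut)
    train <- baseline_set[!baseline_set$outlier, , drop = FALSE]
    stage_log("analyze", sprintf("training set: %d labeled, %d after outlier screen",
                                 nrow(baseline_set), nrow(train)))
    if (length(unique(train$label)) >= 2L) {
      model <- fit_classifier(train, config, seed)
      confusion <- evaluate(model, train)
      stage_log("analyze", sprintf("resubstitution accuracy %.1f%%",
                                   100 * confusion$accuracy))
    } else {
      stage_log("analyze", "fewer than 2 classes after screening; no model fit")
    }
  } else {
    baseline_set$outlier <- rep(FALSE, nrow(baseline_set))
    baseline_set$outlier_reason <- rep(NA_character_, nrow(baseline_set))
    stage_log("analyze", "fewer than 5 labeled subjects; outlier screen and model skipped")
  }
  c(lab, list(baseline_set = baseline_set, model = model,
              confusion = confusion))
}

write_manifest <- function(path, entries) {
  df <- data.frame(key = names(entries),
                   value = vapply(entries, function(v)
                     paste(format(v, digits = 15), collapse = ","), character(1)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Generate a synthetic cohort directory
#'
#' Thin wrapper over [generate_cohort()] that also writes a run manifest.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
run_generate <- function(config = cohort_config(), out_dir) {
  stage_log("generate", sprintf("generating %d subjects into %s",
                                config$n_control + config$n_experimental,
                                out_dir))
  generate_cohort(config, out_dir = out_dir)
  write_manifest(file.path(out_dir, "manifest.tsv"), c(
    stage = "generate",
    package_version = as.character(utils::packageVersion("stressres")),
    seed = config$seed,
    n_control = config$n_control, n_experimental = config$n_experimental,
    subjects = config$n_control + config$n_experimental))
  stage_log("generate", "done")
  invisible(out_dir)
}

#' Analyze a cohort of session directories
#'
#' Reads every subject directory under `session_dir` (EDA is allowed to be
#' missing; such subjects keep their non-EDA features and are excluded from
#' trend analysis), extracts per-phase features, and runs [analyze_cohort()].
#' All stage outputs are written as TSV plus the serialized model and a run
#' manifest.
#'
#' @param session_dir directory of `write_session()` subdirectories.
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @param seed integer seed (classifier shuffle).
#' @return the [analyze_cohort()] result, invisibly.
#' @export
run_analyze <- function(session_dir, out_dir, config = analysis_config(),
                        seed = 1L) {
  subdirs <- list.dirs(session_dir, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "session.tsv"))]
  if (!length(subdirs)) sr_stop("no session directories found")
  stage_log("ingest", sprintf("%d session directories", length(subdirs)))
  feats <- list(); profs <- list()
  for (d in subdirs) {
    s <- read_session(d, allow_missing = "eda")
    feats[[d]] <- suppressWarnings(extract_features(s, config))
    if (!is.null(s$profile)) profs[[d]] <- s$profile
    rm(s)
  }
  features <- do.call(rbind, feats)
  profiles <- do.call(rbind, profs)
  res <- analyze_cohort(features, profiles, config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_features(features, file.path(out_dir, "features.tsv"))
  data.table::fwrite(res$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  data.table::fwrite(res$baseline_set, file.path(out_dir, "baseline_set.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  traj <- do.call(rbind, lapply(res$trajectories, function(tr)
    data.frame(subject_id = tr$subject_id, phase = names(tr$score_by_phase),
               score = unname(tr$score_by_phase), stringsAsFactors = FALSE)))
  if (!is.null(traj))
    data.table::fwrite(traj, file.path(out_dir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(res$model)) {
    write_classifier(res$model, file.path(out_dir, "model.txt"))
    cs <- as.data.frame(res$confusion$confusion)
    data.table::fwrite(cs, file.path(out_dir, "confusion.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(decision_grid(res$model),
                       file.path(out_dir, "decision_grid.tsv"),
                       sep = "\t", quote = FALSE)
  }
  write_manifest(file.path(out_dir, "manifest.tsv"), c(
    stage = "analyze",
    package_version = as.character(utils::packageVersion("stressres")),
    seed = seed, subjects = length(subdirs),
    feature_rows = nrow(features), labeled = nrow(res$labels),
    excluded = nrow(res$excluded),
    accuracy = if (is.null(res$confusion)) NA else res$confusion$accuracy))
  stage_log("analyze", "outputs written to ", out_dir)
  invisible(res)
}

# shared recovery summary: labels vs truth + per-feature errors
recovery_report <- function(features, labels, truth) {
  exp_truth <- truth[truth$group == "experimental", , drop = FALSE]
  cmp <- merge(exp_truth[, c("subject_id", "phenotype")], labels,
               by = "subject_id", all.x = TRUE)
  matched <- sum(!is.na(cmp$label) & cmp$label == cmp$phenotype)
  rate <- matched / nrow(cmp)
  hr_err <- scl_err <- numeric(0)
  for (p in PHASES) {
    tcol <- paste0("hr_", p)
    if (!tcol %in% names(truth)) next
    m <- merge(features[features$phase == p, c("subject_id", "hr_bpm", "scl_us")],
               truth[, c("subject_id", tcol, paste0("scl_", p))],
               by = "subject_id")
    hr_err <- c(hr_err, abs(m$hr_bpm - m[[tcol]]))
    scl_err <- c(scl_err, abs(m$scl_us - m[[paste0("scl_", p)]]))
  }
  list(recovery_rate = rate, n_experimental = nrow(cmp),
       n_matched = matched,
       hr_mae_bpm = mean(hr_err, na.rm = TRUE),
       hr_max_err_bpm = suppressWarnings(max(hr_err, na.rm = TRUE)),
       scl_mae_us = mean(scl_err, na.rm = TRUE),
       comparison = cmp)
}

#' Recover generator ground truth from a cohort directory
#'
#' Re-analyzes a generated cohort and reports how well the pipeline recovers
#' the generator's phenotypes (label-recovery rate) and latent heart-rate /
#' SCL targets (absolute errors).
#'
#' @param session_dir a [run_generate()] output directory (must contain
#'   `ground_truth.tsv`).
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @return list with `recovery_rate`, counts, `hr_mae_bpm`,
#'   `hr_max_err_bpm`, `scl_mae_us`, and the per-subject `comparison` table.
#' @export
run_recover <- function(session_dir, config = analysis_config(), seed = 1L) {
  gt_path <- file.path(session_dir, "ground_truth.tsv")
  if (!file.exists(gt_path)) sr_stop("missing GroundTruth: ", gt_path)
  truth <- as.data.frame(data.table::fread(gt_path, sep = "\t",
                                           na.strings = "NA",
                                           showProgress = FALSE))
  out_dir <- file.path(session_dir, "analysis")
  res <- run_analyze(session_dir, out_dir, config, seed)
  features <- read_features(file.path(out_dir, "features.tsv"))
  rep <- recovery_report(features, res$labels, truth)
  stage_log("recover", sprintf("label recovery %d/%d (%.0f%%), HR MAE %.2f bpm",
                               rep$n_matched, rep$n_experimental,
                               100 * rep$recovery_rate, rep$hr_mae_bpm))
  rep
}

#' End-to-end recovery on an in-memory synthetic cohort
#'
#' Streams [cohort_features()] and [analyze_cohort()] over a generated
#' cohort and compares pipeline labels with the generator's phenotypes,
#' without writing raw signals anywhere.
#'
#' @param config a [cohort_config()].
#' @param analysis an [analysis_config()].
#' @return as [run_recover()], plus the `analysis` result under `$analysis`.
#' @export
recover_cohort <- function(config = cohort_config(),
                           analysis = analysis_config()) {
  co <- cohort_features(config, analysis)
  res <- analyze_cohort(co$features, co$profiles, analysis,
                        seed = config$seed)
  rep <- recovery_report(co$features, res$labels, co$truth)
  rep$analysis <- res
  rep
}
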