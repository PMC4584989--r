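#' Raw physiological channel
#'
#' A single synchronized channel of one subject-session: ECG (mV), EDA
#' (microsiemens), respiration (arbitrary thoracic-expansion units) or
#' trapezius EMG (mV), uniformly sampled. All channels of a session share one
#' sampling rate; the study protocol records at 500 Hz, other rates are
#' permitted. Sample `i` (0-based) covers time `[i/fs, (i+1)/fs)` seconds.
#'
#' @param name one of `"ecg"`, `"eda"`, `"respiration"`, `"emg"`.
#' @param samples numeric vector, at least `2 * sampling_rate` samples.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param unit unit string; defaults to the conventional unit for `name`.
#' @return an object of class `channel_signal`.
#' @export
#' @examples
#' ch <- channel_signal("ecg", rnorm(1000), 500)
#' ch
channel_signal <- function(name, samples, sampling_rate,
                           unit = CHANNEL_UNITS[[name]]) {
  name <- match.arg(name, CHANNEL_NAMES)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    sr_stop("sampling_rate must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 2 * sampling_rate)
    sr_stop(sprintf("channel '%s' must hold at least 2 s of samples", name))
  structure(list(name = name, samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 unit = unit),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$name, x$unit, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Phase annotation table
#'
#' Builds/validates the session phase manifest: half-open `[start_s, end_s)`
#' intervals in seconds from session start, one row per phase. Phases must not
#' overlap. A complete session has a baseline of at least 300 s (the protocol
#' records 5 min of seated baseline).
#'
#' @param phase character vector over `baseline`, `tsst`,
#'   `scenario1`..`scenario5`.
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @return a validated `data.frame` with columns `phase`, `start_s`, `end_s`.
#' @export
phase_annotation <- function(phase, start_s, end_s) {
  ph <- data.frame(phase = as.character(phase),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  bad <- setdiff(ph$phase, PHASES)
  if (length(bad))
    sr_stop(paste0("invalid manifest: unknown phase(s) ",
                   paste(bad, collapse = ", ")), "stressres_manifest_error")
  if (anyDuplicated(ph$phase))
    sr_stop("invalid manifest: duplicated phase", "stressres_manifest_error")
  if (any(!is.finite(ph$start_s)) || any(!is.finite(ph$end_s)) ||
      any(ph$start_s < 0) || any(ph$start_s >= ph$end_s))
    sr_stop("invalid manifest: require 0 <= start_s < end_s",
            "stressres_manifest_error")
  o <- order(ph$start_s)
  ph <- ph[o, , drop = FALSE]
  if (nrow(ph) > 1L && any(ph$start_s[-1L] < ph$end_s[-nrow(ph)] - 1e-9))
    sr_stop("invalid manifest: overlapping phases", "stressres_manifest_error")
  rownames(ph) <- NULL
  ph
}

#' Subject-session recording
#'
#' Bundle of synchronized raw channels plus the phase manifest for one
#' subject. All channels must share one sampling rate and length, and every
#' phase interval must lie within the recorded duration.
#'
#' @param subject_id non-empty subject identifier.
#' @param group `"control"` or `"experimental"`.
#' @param channels list of [channel_signal()] objects (named or not).
#' @param phases a [phase_annotation()] table.
#' @return an object of class `recording`.
#' @export
recording <- function(subject_id, group, channels, phases) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    sr_stop("subject_id must be a non-empty string")
  group <- match.arg(group, c("control", "experimental"))
  if (length(channels) == 0L) sr_stop("recording requires at least one channel")
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_signal")))
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(names(channels))) sr_stop("duplicated channel names")
  fs <- unique(vapply(channels, `[[`, numeric(1), "sampling_rate"))
  if (length(fs) != 1L) sr_stop("all channels must share one sampling_rate")
  len <- unique(vapply(channels, function(c) length(c$samples), integer(1)))
  if (length(len) != 1L) sr_stop("all channels must have equal length")
  phases <- phase_annotation(phases$phase, phases$start_s, phases$end_s)
  dur <- len / fs
  if (any(phases$end_s > dur + 1e-9))
    sr_stop("invalid manifest: phase extends beyond signal duration",
            "stressres_manifest_error")
  if (!"baseline" %in% phases$phase) {
    warning("recording '", subject_id, "' lacks a baseline phase")
  } else {
    b <- phases[phases$phase == "baseline", ]
    if (b$end_s - b$start_s < 300 - 1e-9)
      warning("recording '", subject_id, "' baseline shorter than 300 s")
  }
  structure(list(subject_id = subject_id, group = group,
                 channels = channels, phases = phases,
                 sampling_rate = fs, duration_s = dur),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s (%s): %s @ %g Hz, %.0f s, %d phases\n",
              x$subject_id, x$group,
              paste(names(x$channels), collapse = "+"),
              x$sampling_rate, x$duration_s, nrow(x$phases)))
  invisible(x)
}

#' Phase window of a recording
#'
#' @param rec a [recording()].
#' @param phase phase name present in the manifest.
#' @return `c(start_s, end_s)` of the half-open phase interval.
#' @export
phase_window <- function(rec, phase) {
  row <- rec$phases[rec$phases$phase == phase, ]
  if (nrow(row) != 1L) sr_stop(paste0("phase not annotated: ", phase))
  c(row$start_s, row$end_s)
}

#' Baseline profile of a subject
#'
#' Pre-stressor biomarkers: salivary cortisol (micrograms/dl) and the state
#' portion of the STAI (total 20-80). When individual STAI item responses are
#' supplied they must score to the stated total (items are assumed already
#' keyed, i.e. reverse-keyed statements already mapped).
#'
#' @param subject_id subject identifier.
#' @param cortisol_baseline baseline salivary cortisol, micrograms/dl (>= 0).
#' @param stai_baseline STAI state total in `[20, 80]`.
#' @param cortisol_final optional end-of-session cortisol, micrograms/dl.
#' @param stai_items optional 20 keyed item responses, each in 1-4.
#' @return a one-row `data.frame` of class `baseline_profile` (item responses,
#'   if given, in columns `stai_item_01`..`stai_item_20`).
#' @export
baseline_profile <- function(subject_id, cortisol_baseline, stai_baseline,
                             cortisol_final = NA_real_, stai_items = NULL) {
  if (!is.finite(cortisol_baseline) || cortisol_baseline < 0)
    sr_stop("cortisol_baseline must be >= 0")
  if (!is.na(cortisol_final) && cortisol_final < 0)
    sr_stop("cortisol_final must be >= 0")
  if (!is.finite(stai_baseline) || stai_baseline < 20 || stai_baseline > 80)
    sr_stop("stai_baseline must lie in [20, 80]")
  df <- data.frame(subject_id = subject_id,
                   cortisol_baseline = as.numeric(cortisol_baseline),
                   cortisol_final = as.numeric(cortisol_final),
                   stai_baseline = as.numeric(stai_baseline),
                   stringsAsFactors = FALSE)
  if (!is.null(stai_items)) {
    total <- score_stai(stai_items)
    if (total != stai_baseline)
      sr_stop("stai_items score to a total different from stai_baseline")
    items <- as.list(as.integer(stai_items))
    names(items) <- sprintf("stai_item_%02d", 1:20)
    df <- cbind(df, as.data.frame(items))
  }
  class(df) <- c("baseline_profile", "data.frame")
  df
}

#' Mission log table
#'
#' Per-scenario outcomes of the virtual-environment missions: duration,
#' objectives, shots received, civilian fire, and the scenario time budget
#' (par time) against which overruns are penalized.
#'
#' @param subject_id subject identifier (recycled).
#' @param scenario integer 1-5.
#' @param duration_s mission duration, s.
#' @param objectives_total,objectives_met objective counts,
#'   `0 <= objectives_met <= objectives_total`.
#' @param times_shot,civilian_hits non-negative counts.
#' @param par_time_s scenario time budget, s.
#' @return a validated `data.frame` of class `mission_log`.
#' @export
mission_log <- function(subject_id, scenario, duration_s, objectives_total,
                        objectives_met, times_shot, civilian_hits, par_time_s) {
  df <- data.frame(subject_id = subject_id, scenario = as.integer(scenario),
                   duration_s = as.numeric(duration_s),
                   objectives_total = as.integer(objectives_total),
                   objectives_met = as.integer(objectives_met),
                   times_shot = as.integer(times_shot),
                   civilian_hits = as.integer(civilian_hits),
                   par_time_s = as.numeric(par_time_s),
                   stringsAsFactors = FALSE)
  if (any(df$scenario < 1L | df$scenario > 5L)) sr_stop("scenario must be 1-5")
  if (any(df$duration_s <= 0) || any(df$par_time_s <= 0))
    sr_stop("durations must be positive")
  if (any(df$objectives_total < 0L) || any(df$objectives_met < 0L) ||
      any(df$objectives_met > df$objectives_total))
    sr_stop("require 0 <= objectives_met <= objectives_total")
  if (any(df$times_shot < 0L) || any(df$civilian_hits < 0L))
    sr_stop("counts must be >= 0")
  class(df) <- c("mission_log", "data.frame")
  df
}

# ---- file formats -----------------------------------------------------------
# One delimited text file per channel: "# key: value" header (name, unit,
# sampling_rate) followed by a one-column CSV body; samples printed at fixed
# 1e-6 precision so read->write is byte-stable. Manifest / profile / mission
# tables are plain TSV.

write_channel_file <- function(ch, path) {
  header <- c(sprintf("# name: %s", ch$name),
              sprintf("# unit: %s", ch$unit),
              sprintf("# sampling_rate: %.6g", ch$sampling_rate))
  writeLines(header, path)
  data.table::fwrite(list(value = round(ch$samples, 6)), path,
                     append = TRUE, col.names = TRUE, showProgress = FALSE)
  invisible(path)
}

read_channel_file <- function(path) {
  head_lines <- readLines(path, n = 16L)
  hdr <- head_lines[startsWith(head_lines, "#")]
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta <- setNames(as.list(vals), trimws(keys))
  for (k in c("name", "unit", "sampling_rate"))
    if (is.null(meta[[k]]))
      sr_stop(paste0("channel file missing header key '", k, "': ", path))
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE,
                          showProgress = FALSE)
  name <- meta$name
  expected_unit <- CHANNEL_UNITS[[name]]
  if (!is.null(expected_unit) && !identical(meta$unit, expected_unit))
    sr_stop(sprintf("unit error: channel '%s' declares '%s', expected '%s'",
                    name, meta$unit, expected_unit), "stressres_unit_error")
  channel_signal(name, dt$value, as.numeric(meta$sampling_rate),
                 unit = meta$unit)
}

write_kv_tsv <- function(df, path, digits_cols = NULL) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a subject session to a directory
#'
#' Emits the package's plain-text container for one subject: `<name>.csv` per
#' channel (commented key:value header + one-column body), `phases.tsv`,
#' `session.tsv` (subject id and group), and, when present, `profile.tsv` and
#' `missions.tsv`. Files re-read by [read_session()] reproduce the session to
#' the declared 1e-6 write precision.
#'
#' @param session a `recording`, or a list with elements `recording`,
#'   optionally `profile` (a [baseline_profile()]) and `missions`
#'   (a [mission_log()]).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  if (inherits(session, "recording")) session <- list(recording = session)
  rec <- session$recording
  if (!inherits(rec, "recording")) sr_stop("session must contain a recording")
  if (length(rec$channels) == 0L) sr_stop("empty channel set")
  if (!"baseline" %in% rec$phases$phase)
    warning("writing session without a baseline phase")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) sr_stop(paste0("unwritable path: ", dir))
  for (ch in rec$channels)
    write_channel_file(ch, file.path(dir, paste0(ch$name, ".csv")))
  ph <- rec$phases
  ph$start_s <- sprintf("%.3f", ph$start_s)
  ph$end_s <- sprintf("%.3f", ph$end_s)
  write_kv_tsv(ph, file.path(dir, "phases.tsv"))
  write_kv_tsv(data.frame(key = c("subject_id", "group"),
                          value = c(rec$subject_id, rec$group)),
               file.path(dir, "session.tsv"))
  if (!is.null(session$profile)) {
    pr <- session$profile
    pr$cortisol_baseline <- sprintf("%.4f", pr$cortisol_baseline)
    pr$cortisol_final <- ifelse(is.na(pr$cortisol_final), "NA",
                                sprintf("%.4f", pr$cortisol_final))
    write_kv_tsv(pr, file.path(dir, "profile.tsv"))
  }
  if (!is.null(session$missions)) {
    mi <- session$missions
    mi$duration_s <- sprintf("%.1f", mi$duration_s)
    mi$par_time_s <- sprintf("%.1f", mi$par_time_s)
    write_kv_tsv(mi, file.path(dir, "missions.tsv"))
  }
  invisible(dir)
}

#' Read a subject session from a directory
#'
#' Counterpart of [write_session()]: parses the per-channel files, the phase
#' manifest, and (when present) the baseline profile and mission log, and
#' returns a validated session.
#'
#' @param dir session directory.
#' @param allow_missing channel names that may be absent without error;
#'   the analysis pipeline passes `"eda"` so that subjects with electrodermal
#'   sensor loss are retained for non-EDA features (they are later excluded
#'   from trend analysis). Any other absent channel raises an
#'   "incomplete session" error.
#' @return a list of class `stress_session` with elements `recording`,
#'   `profile` (or `NULL`) and `missions` (or `NULL`).
#' @export
read_session <- function(dir, allow_missing = character()) {
  if (!dir.exists(dir)) sr_stop(paste0("no such session directory: ", dir))
  sess_path <- file.path(dir, "session.tsv")
  if (!file.exists(sess_path)) sr_stop("incomplete session: missing session.tsv")
  meta <- data.table::fread(sess_path, sep = "\t", showProgress = FALSE)
  meta <- setNames(as.list(meta$value), meta$key)
  channels <- list()
  for (nm in CHANNEL_NAMES) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) {
      channels[[nm]] <- read_channel_file(p)
    } else if (!nm %in% allow_missing) {
      sr_stop(paste0("incomplete session: missing channel '", nm, "'"),
              "stressres_session_error")
    }
  }
  ph_path <- file.path(dir, "phases.tsv")
  if (!file.exists(ph_path)) sr_stop("invalid manifest: missing phases.tsv",
                                     "stressres_manifest_error")
  ph <- data.table::fread(ph_path, sep = "\t", showProgress = FALSE)
  rec <- recording(meta$subject_id, meta$group, channels,
                   phase_annotation(ph$phase, ph$start_s, ph$end_s))
  profile <- NULL
  pr_path <- file.path(dir, "profile.tsv")
  if (file.exists(pr_path)) {
    pr <- as.data.frame(data.table::fread(pr_path, sep = "\t",
                                          showProgress = FALSE, na.strings = "NA"))
    items <- grep("^stai_item_", names(pr), value = TRUE)
    profile <- baseline_profile(pr$subject_id, pr$cortisol_baseline,
                                pr$stai_baseline,
                                cortisol_final = pr$cortisol_final %||% NA_real_,
                                stai_items = if (length(items) == 20L)
                                  as.integer(pr[1, items]) else NULL)
  }
  missions <- NULL
  mi_path <- file.path(dir, "missions.tsv")
  if (file.exists(mi_path)) {
    mi <- as.data.frame(data.table::fread(mi_path, sep = "\t",
                                          showProgress = FALSE))
    missions <- mission_log(mi$subject_id, mi$scenario, mi$duration_s,
                            mi$objectives_total, mi$objectives_met,
                            mi$times_shot, mi$civilian_hits, mi$par_time_s)
  }
  structure(list(recording = rec, profile = profile, missions = missions),
            class = "stress_session")
}
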