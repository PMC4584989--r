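#' Analysis configuration
#'
#' Every filter order, band edge, threshold and window used by the feature,
#' scoring and classifier stages, with the package defaults. Values can be
#' overridden by name; unknown keys are rejected.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{ecg.band_hz}{R-peak energy band-pass edges, `c(5, 15)` Hz.}
#'   \item{ecg.filter_order}{Butterworth order for the energy band-pass, 2.}
#'   \item{ecg.integration_s}{moving-window integration length, 0.15 s.}
#'   \item{ecg.refractory_s}{minimum R-R separation during detection, 0.24 s.}
#'   \item{hr.min_bpm, hr.max_bpm}{instantaneous-rate validity bounds, 40 and
#'     180 bpm; R-R intervals outside them are masked invalid.}
#'   \item{hrv.resample_hz}{tachogram resampling rate, 4 Hz.}
#'   \item{hrv.lf_band_hz, hrv.hf_band_hz}{LF `[0.04, 0.15)` and HF
#'     `[0.15, 0.4]` Hz integration bands.}
#'   \item{hrv.welch_segment_s, hrv.welch_overlap}{Welch segment length 64 s,
#'     overlap fraction 0.5 (Hann window).}
#'   \item{eda.decimate_hz}{working rate for electrodermal filtering, 4 Hz.}
#'   \item{eda.band_hz}{phasic band-pass edges, `c(0.05, 1)` Hz.}
#'   \item{eda.filter_order}{Butterworth order, 4 (zero-phase).}
#'   \item{eda.threshold_us}{EDR onset threshold, 0.05 microsiemens.}
#'   \item{eda.hysteresis_us}{Schmitt-trigger band below the onset threshold,
#'     0.001 microsiemens.}
#'   \item{eda.refractory_s}{minimum separation of EDR onsets, 1 s.}
#'   \item{eda.tonic_cut_hz}{low-pass cut for the tonic (SCL) component,
#'     0.05 Hz.}
#'   \item{resp.band_hz, resp.filter_order, resp.decimate_hz}{respiration
#'     band-pass `c(0.05, 1)` Hz, order 4, at a 4 Hz working rate.}
#'   \item{emg.block_s}{RMS block length, 0.2 s (100 samples at 500 Hz).}
#'   \item{sdnn.population}{logical; use the n denominator (TRUE).}
#'   \item{sdnn.min_window_s}{preferred SDNN window, 300 s; shorter windows
#'     are computed but flagged.}
#'   \item{stress_score.hr_weight}{weight of the heart-rate ratio in the
#'     stress score, 0.5 (SCL gets the complement).}
#'   \item{stress_score.normalization}{`"per_phase"` control means (default)
#'     or `"grand"` (one control mean per measure).}
#'   \item{trend.threshold_pct}{percent-change threshold of the trend rules,
#'     5.}
#'   \item{trend.scenario_aggregate}{scenario summary entering the rules:
#'     `"mean"` (default), `"last"` or `"max"`.}
#'   \item{performance.w_shot, performance.w_civ, performance.w_time}{mission
#'     score penalty weights, 0.5, 2 and 2.}
#'   \item{classifier.alpha}{L2 penalty weight of the SGD model, 1e-4.}
#'   \item{classifier.max_epochs, classifier.tol}{epoch cap 1000, stopping
#'     tolerance 1e-3 (5 epochs without improvement).}
#'   \item{classifier.standardize}{standardize features before SGD (TRUE).}
#'   \item{outlier.z_cut}{robust z-score cut of the outlier screen, 2.5.}
#' }
#'
#' @return a named list of class `stressres_config`.
#' @export
#' @examples
#' cfg <- analysis_config(trend.threshold_pct = 10)
#' cfg$trend.threshold_pct
analysis_config <- function(...) {
  defaults <- list(
    ecg.band_hz = c(5, 15),
    ecg.filter_order = 2L,
    ecg.integration_s = 0.15,
    ecg.refractory_s = 0.24,
    hr.min_bpm = 40,
    hr.max_bpm = 180,
    hrv.resample_hz = 4,
    hrv.lf_band_hz = c(0.04, 0.15),
    hrv.hf_band_hz = c(0.15, 0.4),
    hrv.welch_segment_s = 64,
    hrv.welch_overlap = 0.5,
    eda.decimate_hz = 4,
    eda.band_hz = c(0.05, 1),
    eda.filter_order = 4L,
    eda.threshold_us = 0.05,
    eda.hysteresis_us = 0.001,
    eda.refractory_s = 1,
    eda.tonic_cut_hz = 0.05,
    resp.band_hz = c(0.05, 1),
    resp.filter_order = 4L,
    resp.decimate_hz = 4,
    emg.block_s = 0.2,
    sdnn.population = TRUE,
    sdnn.min_window_s = 300,
    stress_score.hr_weight = 0.5,
    stress_score.normalization = "per_phase",
    trend.threshold_pct = 5,
    trend.scenario_aggregate = "mean",
    performance.w_shot = 0.5,
    performance.w_civ = 2,
    performance.w_time = 2,
    classifier.alpha = 1e-4,
    classifier.max_epochs = 1000L,
    classifier.tol = 1e-3,
    classifier.standardize = TRUE,
    outlier.z_cut = 2.5
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) sr_stop(paste0("unknown config key(s): ",
                                    paste(bad, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "stressres_config")
}

#' Read / write a configuration as a flat key-value file
#'
#' One `key<TAB>value` pair per line; vector values are comma separated.
#'
#' @param config a [analysis_config()] list.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `stressres_config`.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                character(1))
  writeLines(paste(names(config), fmt, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- lapply(kv, function(p) {
    parts <- strsplit(p[2L], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else if (all(parts %in% c("TRUE", "FALSE")))
      as.logical(parts) else parts
  })
  do.call(analysis_config, setNames(vals, keys))
}
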