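#' R-peak detection on the ECG channel
#'
#' Pan-Tompkins-style detector: band-pass energy (5-15 Hz), squared
#' derivative, moving-window integration, adaptive thresholding of integrated
#' energy, then refinement of each candidate to the raw-signal maximum within
#' +/- 75 ms (so peak times land on the true R maxima of clean signals to
#' within one sample). R-R intervals whose instantaneous rate falls outside
#' 40-180 bpm are masked invalid and excluded from all downstream statistics.
#'
#' @param ecg an ECG [channel_signal()] of at least 10 s.
#' @param config an [analysis_config()].
#' @return an object of class `beat_series`: list with `r_peak_times_s`
#'   (strictly increasing), `rr_intervals_s` (one fewer), `rr_valid_mask`.
#' @export
#' @examples
#' ecg <- synth_ecg(hr_bpm = 60, duration_s = 30, seed = 1)
#' b <- detect_r_peaks(ecg)
#' range(b$rr_intervals_s)
detect_r_peaks <- function(ecg, config = analysis_config()) {
  stopifnot(inherits(ecg, "channel_signal"))
  fs <- ecg$sampling_rate
  x <- ecg$samples
  if (length(x) < 10 * fs) sr_stop("ECG shorter than 10 s")
  if (all(is.na(x)) || isTRUE(sd_pop(x[is.finite(x)]) == 0))
    sr_stop("undetectable rhythm", "stressres_signal_error")
  x[!is.finite(x)] <- 0
  # causal band-pass energy; group delay is irrelevant because peak positions
  # are refined on the raw trace afterwards
  bf <- signal::butter(config$ecg.filter_order,
                       config$ecg.band_hz / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, x))
  en <- c(0, diff(y))^2
  w <- max(1L, round(config$ecg.integration_s * fs))
  cs <- cumsum(en)
  mwi <- (cs - c(rep(0, w), head(cs, -w))) / w
  thr <- 0.3 * as.numeric(quantile(mwi, 0.99))
  if (thr <= 0) sr_stop("undetectable rhythm", "stressres_signal_error")
  above <- mwi > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1L)
  ends <- which(edges == -1L) - 1L
  if (length(starts) < 2L) sr_stop("undetectable rhythm", "stressres_signal_error")
  cand <- as.integer(mapply(function(s, e) s - 1L + which.max(mwi[s:e]),
                            starts, ends))
  # enforce refractory separation, keeping the stronger of close candidates
  min_gap <- round(config$ecg.refractory_s * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < min_gap) {
      if (mwi[i] > mwi[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # Refine to the raw R maximum. The causal band-pass + derivative +
  # integration stages place the energy candidate ~60-150 ms after the R
  # peak, so the search window reaches back over that lag (and only
  # marginally forward, to stay clear of the T wave and, at high rates,
  # the next beat).
  back <- as.integer(round(0.18 * fs))
  fwd <- as.integer(round(0.02 * fs))
  n <- length(x)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - back); hi <- min(n, i + fwd)
    lo - 1L + which.max(x[lo:hi])
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) > 1L) {
    gap_ok <- c(TRUE, diff(peaks) >= min_gap)
    peaks <- peaks[gap_ok]
  }
  if (length(peaks) < 2L) sr_stop("undetectable rhythm", "stressres_signal_error")
  times <- (peaks - 1L) / fs
  rr <- diff(times)
  valid <- 60 / rr >= config$hr.min_bpm & 60 / rr <= config$hr.max_bpm
  structure(list(r_peak_times_s = times, rr_intervals_s = rr,
                 rr_valid_mask = valid),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d/%d valid RR\n",
              length(x$r_peak_times_s), sum(x$rr_valid_mask),
              length(x$rr_intervals_s)))
  invisible(x)
}

# valid RR intervals whose terminating beat falls inside [start, end)
window_rr <- function(beats, window) {
  ends <- beats$r_peak_times_s[-1L]
  sel <- beats$rr_valid_mask & ends >= window[1] & ends < window[2]
  list(rr = beats$rr_intervals_s[sel], t = ends[sel])
}

#' Mean heart rate over a phase window
#'
#' `60 / mean(valid R-R)` over the intervals terminating inside the half-open
#' window; intervals masked by the 40-180 bpm rule are ignored.
#'
#' @param beats a [detect_r_peaks()] result.
#' @param window `c(start_s, end_s)`.
#' @return heart rate in bpm, or `NA` (with a message) when fewer than two
#'   valid intervals fall in the window.
#' @export
mean_heart_rate <- function(beats, window) {
  w <- window_rr(beats, window)
  if (length(w$rr) < 2L) {
    stage_log("features", "mean_heart_rate: <2 valid RR in window, NA")
    return(NA_real_)
  }
  60 / mean(w$rr)
}

#' SDNN over a phase window
#'
#' Standard deviation of the valid R-R intervals, in milliseconds. The n
#' (population) denominator is used by default (`sdnn.population`). Windows
#' shorter than `sdnn.min_window_s` (default 300 s, matching the convention
#' of computing SDNN over more than 5 min) are computed but flagged with a
#' `short_window` attribute and a warning.
#'
#' @inheritParams mean_heart_rate
#' @param config an [analysis_config()].
#' @return SDNN in ms (`NA` when fewer than two valid intervals).
#' @export
sdnn <- function(beats, window, config = analysis_config()) {
  short <- diff(window) < config$sdnn.min_window_s
  if (short) warning(sprintf("SDNN window %.0f s is shorter than %g s",
                             diff(window), config$sdnn.min_window_s))
  w <- window_rr(beats, window)
  if (length(w$rr) < 2L) return(NA_real_)
  v <- if (isTRUE(config$sdnn.population)) sd_pop(w$rr) else sd(w$rr)
  structure(v * 1000, short_window = short)
}

# Hann-window Welch PSD; x sampled at fs, segment length nseg, overlap frac.
welch_psd <- function(x, fs, nseg, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(win^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    p <- abs(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist when nseg even)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd * dbl)
}

#' Frequency-domain heart-rate variability over a phase window
#'
#' The valid R-R tachogram is linearly resampled to an even grid
#' (`hrv.resample_hz`, default 4 Hz), linearly detrended, and its Welch
#' power spectrum (Hann window, 64 s segments, 50% overlap) integrated over
#' the low-frequency `[0.04, 0.15)` Hz and high-frequency `[0.15, 0.4]` Hz
#' bands by rectangular summation. Powers are in ms^2; their ratio is
#' dimensionless.
#'
#' @inheritParams sdnn
#' @return list with `lf_power`, `hf_power`, `lf_hf_ratio` (`NA` ratio when
#'   HF power is zero; all `NA` when the window holds under 120 s of valid
#'   beats).
#' @export
hrv_spectrum <- function(beats, window, config = analysis_config()) {
  w <- window_rr(beats, window)
  na <- list(lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_)
  if (length(w$rr) < 4L) return(na)
  span <- max(w$t) - min(w$t)
  if (span < 120) {
    stage_log("features", "hrv_spectrum: <120 s of valid beats, NA")
    return(na)
  }
  fs <- config$hrv.resample_hz
  grid <- seq(min(w$t), max(w$t), by = 1 / fs)
  tach <- approx(w$t, w$rr * 1000, xout = grid, rule = 2)$y
  # linear detrend
  tt <- seq_along(tach)
  fit <- stats::lm.fit(cbind(1, tt), tach)
  tach <- tach - fit$fitted.values
  nseg <- round(config$hrv.welch_segment_s * fs)
  sp <- welch_psd(tach, fs, nseg, config$hrv.welch_overlap)
  df <- sp$freq[2L] - sp$freq[1L]
  lf_b <- config$hrv.lf_band_hz; hf_b <- config$hrv.hf_band_hz
  lf <- sum(sp$psd[sp$freq >= lf_b[1] & sp$freq < lf_b[2]]) * df
  hf <- sum(sp$psd[sp$freq >= hf_b[1] & sp$freq <= hf_b[2]]) * df
  list(lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

# Zero-phase filtering with odd-reflection edge padding: signal::filtfilt
# starts from zero state, so low-frequency filters ring at the signal edges
# (a constant input would not come back constant). Reflecting ~60 s of
# signal about each endpoint before filtering suppresses the transient.
pad_filtfilt <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(filt, xp))
  y[(pad + 1L):(pad + n)]
}

# decimate + zero-phase band-pass at a low working rate
bandpass_decimated <- function(x, fs, band, order, work_hz) {
  block <- max(1L, round(fs / work_hz))
  xd <- block_decimate(x, block)
  fd <- fs / block
  bf <- signal::butter(order, band / (fd / 2), type = "pass")
  pad <- round(60 * fd)
  list(x = pad_filtfilt(bf, xd, pad), fs = fd, raw = xd)
}

#' Respiratory cycle detection
#'
#' The respiration channel is decimated to a low working rate, band-passed to
#' 0.05-1 Hz (zero-phase Butterworth), and inspiration onsets are taken as
#' rising zero crossings (linearly interpolated between samples). The
#' breathing rate is `60 / mean(cycle duration)`.
#'
#' @param resp a respiration [channel_signal()].
#' @param window `c(start_s, end_s)`, at least 30 s.
#' @param config an [analysis_config()].
#' @return an object of class `resp_cycle_series` with `cycle_boundaries_s`
#'   (inspiration-onset times) and `rate_breaths_per_min`, or `NA` (logged)
#'   when no full cycle is detectable.
#' @export
respiratory_cycles <- function(resp, window, config = analysis_config()) {
  stopifnot(inherits(resp, "channel_signal"))
  if (diff(window) < 30) sr_stop("respiration window must be >= 30 s")
  bd <- bandpass_decimated(resp$samples, resp$sampling_rate,
                           config$resp.band_hz, config$resp.filter_order,
                           config$resp.decimate_hz)
  t <- (seq_along(bd$x) - 0.5) / bd$fs
  sel <- t >= window[1] & t < window[2]
  xs <- bd$x[sel]; ts <- t[sel]
  raw_sel <- bd$raw[sel]
  # a DC or drift-only trace leaves almost nothing in the breathing band
  # (the comparison is relative: the filter leaks ~1e-4 numerically even on
  # a constant input)
  if (length(xs) < 2L || diff(range(raw_sel)) <= 0 ||
      sd_pop(xs) <= 1e-3 * sd_pop(raw_sel)) {
    stage_log("features", "respiratory_cycles: no detectable cycles, NA")
    return(NA)
  }
  up <- which(xs[-length(xs)] < 0 & xs[-1L] >= 0)
  if (length(up) < 2L) {
    stage_log("features", "respiratory_cycles: no full cycle, NA")
    return(NA)
  }
  frac <- -xs[up] / (xs[up + 1L] - xs[up])
  onsets <- ts[up] + frac / bd$fs
  rate <- 60 / mean(diff(onsets))
  structure(list(cycle_boundaries_s = onsets, rate_breaths_per_min = rate),
            class = "resp_cycle_series")
}

#' Peak-valley respiratory sinus arrhythmia
#'
#' For each respiratory cycle, the instantaneous heart rate (stepwise 60/RR
#' assigned to the interval's terminating beat) is evaluated over the beats
#' whose R peak falls inside the cycle; the cycle's RSA is the maximum minus
#' the minimum rate. Cycles holding fewer than two beats are skipped, and the
#' subject-level value is the mean over qualifying cycles.
#'
#' @param beats a [detect_r_peaks()] result.
#' @param cycles a [respiratory_cycles()] result.
#' @return RSA in bpm, or `NA` when fewer than 3 qualifying cycles exist.
#' @export
rsa_peak_valley <- function(beats, cycles) {
  if (!inherits(cycles, "resp_cycle_series")) return(NA_real_)
  b <- cycles$cycle_boundaries_s
  if (length(b) < 2L) return(NA_real_)
  ends <- beats$r_peak_times_s[-1L]
  hr <- 60 / beats$rr_intervals_s
  hr[!beats$rr_valid_mask] <- NA_real_
  ranges <- numeric(0)
  for (j in seq_len(length(b) - 1L)) {
    in_cycle <- hr[ends >= b[j] & ends < b[j + 1L]]
    in_cycle <- in_cycle[is.finite(in_cycle)]
    if (length(in_cycle) >= 2L)
      ranges <- c(ranges, max(in_cycle) - min(in_cycle))
  }
  if (length(ranges) < 3L) {
    stage_log("features", "rsa_peak_valley: <3 qualifying cycles, NA")
    return(NA_real_)
  }
  mean(ranges)
}

#' Electrodermal response detection and tonic level
#'
#' The EDA channel is decimated to a low working rate; the phasic component
#' is the 0.05-1 Hz zero-phase band-pass, and an electrodermal response (EDR)
#' is an upward crossing of the 0.05 microsiemens onset threshold. A Schmitt
#' trigger closes the event only once the phasic signal falls below
#' threshold minus the 0.001 microsiemens hysteresis band, and a 1 s
#' refractory period separates onsets. The tonic skin conductance level (SCL)
#' is the mean of the sub-0.05 Hz low-passed raw signal over the window.
#'
#' @param eda an EDA [channel_signal()].
#' @param window `c(start_s, end_s)`, at least 60 s.
#' @param config an [analysis_config()].
#' @return an object of class `edr_series`: `event_times_s`, `rate_per_min`
#'   (= count / window minutes), `scl_tonic_us`.
#' @export
detect_edr <- function(eda, window, config = analysis_config()) {
  stopifnot(inherits(eda, "channel_signal"))
  if (diff(window) < 60) sr_stop("EDA window must be >= 60 s")
  fs <- eda$sampling_rate
  x <- eda$samples
  flat <- all(is.na(x)) || isTRUE(sd_pop(x[is.finite(x)]) == 0)
  if (flat) warning("EDA signal is flat or saturated; EDR rate set to 0")
  bd <- bandpass_decimated(x, fs, config$eda.band_hz,
                           config$eda.filter_order, config$eda.decimate_hz)
  lp <- signal::butter(config$eda.filter_order,
                       config$eda.tonic_cut_hz / (bd$fs / 2), type = "low")
  tonic <- pad_filtfilt(lp, bd$raw, round(60 * bd$fs))
  t <- (seq_along(bd$x) - 0.5) / bd$fs
  sel <- t >= window[1] & t < window[2]
  scl <- mean(tonic[sel])
  events <- numeric(0)
  if (!flat) {
    thr <- config$eda.threshold_us
    lo <- thr - config$eda.hysteresis_us
    open <- FALSE
    last_onset <- -Inf
    xs <- bd$x[sel]; ts <- t[sel]
    for (i in seq_along(xs)) {
      if (!open && xs[i] >= thr) {
        if (ts[i] - last_onset >= config$eda.refractory_s) {
          events <- c(events, ts[i])
          last_onset <- ts[i]
        }
        open <- TRUE
      } else if (open && xs[i] < lo) {
        open <- FALSE
      }
    }
  }
  structure(list(event_times_s = events,
                 rate_per_min = length(events) / (diff(window) / 60),
                 scl_tonic_us = scl),
            class = "edr_series")
}

#' Block-averaged EMG root mean square
#'
#' RMS computed in non-overlapping 0.2 s blocks (100 samples at 500 Hz),
#' then averaged over the window; trailing partial blocks are dropped.
#'
#' @param emg an EMG [channel_signal()].
#' @param window `c(start_s, end_s)`, at least 1 s.
#' @param config an [analysis_config()].
#' @return mean block RMS in the channel's unit (mV).
#' @export
emg_rms <- function(emg, window, config = analysis_config()) {
  stopifnot(inherits(emg, "channel_signal"))
  if (diff(window) < 1) sr_stop("EMG window must be >= 1 s")
  fs <- emg$sampling_rate
  idx <- window_indices(length(emg$samples), fs, window[1], window[2])
  x <- emg$samples[idx]
  block <- max(1L, round(config$emg.block_s * fs))
  n <- (length(x) %/% block) * block
  if (n == 0L) return(NA_real_)
  m <- matrix(x[seq_len(n)]^2, nrow = block)
  mean(sqrt(colMeans(m)))
}

#' Per-phase autonomic feature table of a session
#'
#' Runs every detector once per recording and summarizes each annotated phase
#' into one feature vector: heart rate, SDNN, LF/HF spectral powers and
#' ratio, peak-valley RSA, respiration rate, SCL, EDR rate and EMG RMS.
#' Missing channels or undetectable components yield `NA` features (logged),
#' never errors.
#'
#' @param session a `recording` or a `stress_session` (the recording is
#'   used; subject id and group are carried into the table).
#' @param config an [analysis_config()].
#' @return a `data.frame`, one row per phase, columns `subject_id`, `group`,
#'   `phase`, `hr_bpm`, `sdnn_ms`, `lf_power`, `hf_power`, `lf_hf_ratio`,
#'   `rsa_bpm`, `resp_rate_bpm`, `scl_us`, `edr_per_min`, `emg_rms_mv`.
#' @export
extract_features <- function(session, config = analysis_config()) {
  rec <- if (inherits(session, "recording")) session else session$recording
  stopifnot(inherits(rec, "recording"))
  beats <- NULL
  if (!is.null(rec$channels$ecg))
    beats <- tryCatch(detect_r_peaks(rec$channels$ecg, config),
                      error = function(e) {
                        stage_log("features", "R-peak detection failed: ",
                                  conditionMessage(e))
                        NULL
                      })
  rows <- lapply(seq_len(nrow(rec$phases)), function(i) {
    ph <- rec$phases$phase[i]
    win <- c(rec$phases$start_s[i], rec$phases$end_s[i])
    hr <- sdnn_ms <- rsa <- NA_real_
    spec <- list(lf_power = NA_real_, hf_power = NA_real_,
                 lf_hf_ratio = NA_real_)
    resp_rate <- scl <- edr <- rms <- NA_real_
    cycles <- NA
    if (!is.null(beats)) {
      hr <- mean_heart_rate(beats, win)
      sdnn_ms <- suppressWarnings(as.numeric(sdnn(beats, win, config)))
      spec <- hrv_spectrum(beats, win, config)
    }
    if (!is.null(rec$channels$respiration) && diff(win) >= 30) {
      cycles <- respiratory_cycles(rec$channels$respiration, win, config)
      if (inherits(cycles, "resp_cycle_series")) {
        resp_rate <- cycles$rate_breaths_per_min
        if (!is.null(beats)) rsa <- rsa_peak_valley(beats, cycles)
      }
    }
    if (!is.null(rec$channels$eda) && diff(win) >= 60) {
      ed <- detect_edr(rec$channels$eda, win, config)
      scl <- ed$scl_tonic_us
      edr <- ed$rate_per_min
    }
    if (!is.null(rec$channels$emg) && diff(win) >= 1)
      rms <- emg_rms(rec$channels$emg, win, config)
    data.frame(subject_id = rec$subject_id, group = rec$group, phase = ph,
               hr_bpm = hr, sdnn_ms = sdnn_ms,
               lf_power = spec$lf_power, hf_power = spec$hf_power,
               lf_hf_ratio = spec$lf_hf_ratio, rsa_bpm = rsa,
               resp_rate_bpm = resp_rate, scl_us = scl, edr_per_min = edr,
               emg_rms_mv = rms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$phase <- factor(out$phase, levels = PHASES)
  out <- out[order(out$phase), , drop = FALSE]
  out$phase <- as.character(out$phase)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as TSV
#' @param features a feature table from [extract_features()] (rows from many
#'   subjects may be bound together).
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                  showProgress = FALSE))
}
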