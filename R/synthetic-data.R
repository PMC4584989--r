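# truncated-normal draw by inverse-CDF
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, pl, pu), mean, sd)
}

# truncated log-normal draw parameterized by its (untruncated) mean and SD
rtlnorm <- function(n, mean, sd, lower = 0.02, upper = 2.5) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pl <- stats::plnorm(lower, meanlog, sdlog)
  pu <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(runif(n, pl, pu), meanlog, sdlog)
}

#' Phenotype specifications of the synthetic cohort
#'
#' One row per resilience phenotype, giving the latent heart-rate and SCL
#' reactivity (percent rise at the TSST) and residual (percent above baseline
#' during scenarios), and the phenotype-conditioned baseline-biomarker
#' distributions. The defaults encode the defining trend rules (resistant
#' reactivity below the 5% threshold; recovery residual above it with the
#' scenario level below the TSST level) and the observed baseline gradient:
#' resistant phenotypes draw higher cortisol and lower STAI, recovery the
#' reverse, resilient intermediate. Under the default 12/3/4 mixture the
#' cohort moments approximate baseline cortisol 0.38 +/- 0.28 micrograms/dl
#' and baseline STAI 30 +/- 9.
#'
#' @param separation class-separation multiplier for the biomarker
#'   distributions: phenotype means are pushed away from the mixture grand
#'   mean by this factor and within-class SDs divided by it. `1` reproduces
#'   the cohort-calibrated defaults; larger values give well-separated
#'   classes for classifier-geometry studies.
#' @return `data.frame` with one row per label.
#' @export
phenotype_specs <- function(separation = 1) {
  sp <- data.frame(
    label = c("resistant", "resilient", "recovery", "dysfunctional"),
    hr_reactivity_pct = c(2, 30, 30, 30),
    hr_residual_pct = c(0, 1, 15, 40),
    scl_reactivity_pct = c(2, 30, 30, 30),
    scl_residual_pct = c(0, 1, 15, 40),
    cortisol_mean = c(0.54, 0.36, 0.24, 0.24),
    cortisol_sd = c(0.35, 0.24, 0.16, 0.16),
    stai_mean = c(26, 29.5, 35, 36),
    stai_sd = c(7, 7, 8, 8),
    stringsAsFactors = FALSE)
  if (separation != 1) {
    w <- c(resistant = 3, resilient = 12, recovery = 4, dysfunctional = 0)
    w <- w[sp$label] / sum(w)
    for (col in c("cortisol_mean", "stai_mean")) {
      grand <- sum(w * sp[[col]])
      sp[[col]] <- grand + (sp[[col]] - grand) * separation
    }
    sp$cortisol_mean <- pmax(sp$cortisol_mean, 0.02)
    sp$cortisol_sd <- sp$cortisol_sd / separation
    sp$stai_sd <- sp$stai_sd / separation
  }
  stopifnot(all(sp$hr_reactivity_pct[sp$label == "resistant"] <= 5),
            all(sp$hr_residual_pct[sp$label == "resilient"] <= 5),
            all(sp$hr_residual_pct[sp$label %in% c("recovery", "dysfunctional")] > 5))
  sp
}

#' Synthetic-cohort configuration
#'
#' Study-design parameters of the generator: group sizes (20 control, 19
#' experimental), phenotype mixture (12/19 resilient, 3/19 resistant, 4/19
#' recovery), phase durations (300 s baseline, 900 s TSST - three 5-min
#' blocks of anticipation, speech and arithmetic - and 600 s per scenario),
#' channel noise scales, and the master seed that fully determines every
#' draw.
#'
#' @param n_control,n_experimental group sizes.
#' @param phenotype_mix named proportions over the phenotype labels; must
#'   sum to 1.
#' @param baseline_s,tsst_s,scenario_s phase durations in seconds.
#' @param sampling_rate channel sampling rate, Hz.
#' @param rr_jitter_ms SD of the Gaussian R-R jitter, ms.
#' @param ecg_noise_mv,eda_noise_us,resp_noise SD of additive channel noise.
#' @param scl_drift_us amplitude of the slow (< 0.02 Hz) tonic drift.
#' @param scr_amplitude_us amplitude of generated skin-conductance
#'   responses (detectable when >= 0.05).
#' @param phase_wiggle_pct SD of the per-phase multiplicative jitter applied
#'   to latent heart-rate/SCL targets, percent.
#' @param noise_scale master multiplier over all the noise terms above
#'   (0 = noiseless signals; phenotype and subject-level draws are not
#'   affected).
#' @param separation biomarker class separation (see [phenotype_specs()]).
#' @param seed master integer seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 20L, n_experimental = 19L,
                          phenotype_mix = c(resilient = 12 / 19,
                                            resistant = 3 / 19,
                                            recovery = 4 / 19),
                          baseline_s = 300, tsst_s = 900, scenario_s = 600,
                          sampling_rate = 500,
                          rr_jitter_ms = 20, ecg_noise_mv = 0.02,
                          eda_noise_us = 0.01, resp_noise = 0.05,
                          scl_drift_us = 0.08, scr_amplitude_us = 0.3,
                          phase_wiggle_pct = 1.5, noise_scale = 1,
                          separation = 1, seed = 1L) {
  if (!is_count(n_control) || !is_count(n_experimental))
    sr_stop("group sizes must be non-negative integers")
  if (is.null(names(phenotype_mix)) ||
      !all(names(phenotype_mix) %in% RESILIENCE_LABELS))
    sr_stop("phenotype_mix must be named over the resilience labels")
  if (abs(sum(phenotype_mix) - 1) > 1e-8)
    sr_stop("phenotype_mix proportions must sum to 1")
  structure(list(n_control = as.integer(n_control),
                 n_experimental = as.integer(n_experimental),
                 phenotype_mix = phenotype_mix,
                 baseline_s = baseline_s, tsst_s = tsst_s,
                 scenario_s = scenario_s, sampling_rate = sampling_rate,
                 rr_jitter_ms = rr_jitter_ms, ecg_noise_mv = ecg_noise_mv,
                 eda_noise_us = eda_noise_us, resp_noise = resp_noise,
                 scl_drift_us = scl_drift_us,
                 scr_amplitude_us = scr_amplitude_us,
                 phase_wiggle_pct = phase_wiggle_pct,
                 noise_scale = noise_scale, separation = separation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# default 7-phase manifest for a config
config_phases <- function(config) {
  durs <- c(config$baseline_s, config$tsst_s, rep(config$scenario_s, 5))
  ends <- cumsum(durs)
  phase_annotation(PHASES, c(0, head(ends, -1)), ends)
}

# per-phase value helper: expand scalar or named per-phase vector over phases
phase_values <- function(x, phases) {
  if (length(x) == 1L) return(rep(as.numeric(x), nrow(phases)))
  if (!is.null(names(x))) return(as.numeric(x[phases$phase]))
  stopifnot(length(x) == nrow(phases))
  as.numeric(x)
}

#' Synthetic ECG channel
#'
#' Beat train whose instantaneous rate follows per-phase targets plus a
#' sinusoidal respiratory modulation (the RSA component) and Gaussian R-R
#' jitter, rendered as template QRS complexes (Gaussian R wave with Q/S
#' dips and a low T wave) at the sampling rate.
#'
#' @param hr_bpm target heart rate: scalar, or per-phase named vector used
#'   with `phases`.
#' @param duration_s signal length in seconds (ignored when `phases` given).
#' @param phases optional [phase_annotation()] table.
#' @param rsa_amplitude_bpm peak-to-peak respiratory modulation of the
#'   instantaneous rate, bpm.
#' @param resp_rate_bpm respiration rate driving the modulation,
#'   breaths/min (scalar or per-phase).
#' @param rr_jitter_ms SD of additive Gaussian R-R jitter, ms.
#' @param noise_mv SD of additive broadband measurement noise, mV.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return an ECG [channel_signal()] with attribute `beat_times_s` (the true
#'   R times).
#' @export
#' @examples
#' ecg <- synth_ecg(60, duration_s = 60, seed = 2)
#' length(attr(ecg, "beat_times_s"))
synth_ecg <- function(hr_bpm, duration_s = NULL, phases = NULL,
                      rsa_amplitude_bpm = 0, resp_rate_bpm = 15,
                      rr_jitter_ms = 0, noise_mv = 0, fs = 500, seed = 1L) {
  if (is.null(phases)) {
    stopifnot(!is.null(duration_s))
    phases <- phase_annotation("baseline", 0, duration_s)
  }
  dur <- max(phases$end_s)
  hr_p <- phase_values(hr_bpm, phases)
  f_p <- phase_values(resp_rate_bpm, phases) / 60
  stopifnot(all(hr_p >= 40), all(hr_p <= 180))
  hr_at <- stats::approxfun(phases$start_s, hr_p, method = "constant",
                            rule = 2)
  f_at <- stats::approxfun(phases$start_s, f_p, method = "constant", rule = 2)
  beats <- with_seed(seed, {
    t <- runif(1, 0, 0.5)   # random first-beat offset
    out <- numeric(ceiling(dur * 4))
    k <- 0L
    while (t < dur) {
      k <- k + 1L
      out[k] <- t
      hr_inst <- hr_at(t) + rsa_amplitude_bpm / 2 * sin(2 * pi * f_at(t) * t)
      rr <- 60 / hr_inst + rnorm(1, 0, rr_jitter_ms / 1000)
      t <- t + max(rr, 0.25)
    }
    out[seq_len(k)]
  })
  n <- ceiling(dur * fs)
  x <- numeric(n)
  tau <- seq(-0.05, 0.25, by = 1 / fs)
  template <- exp(-(tau / 0.008)^2) -
    0.15 * exp(-((tau + 0.025) / 0.012)^2) -
    0.12 * exp(-((tau - 0.030) / 0.012)^2) +
    0.15 * exp(-((tau - 0.180) / 0.060)^2)
  off <- which.max(template) - 1L
  for (bt in beats) {
    i0 <- round(bt * fs) + 1L - off
    idx <- seq(i0, i0 + length(template) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  if (noise_mv > 0)
    x <- x + with_seed(seed + 1L, rnorm(n, 0, noise_mv))
  ch <- channel_signal("ecg", x, fs)
  attr(ch, "beat_times_s") <- beats
  ch
}

#' Synthetic electrodermal channel
#'
#' Tonic level following per-phase targets (smoothed across phase boundaries)
#' plus a slow sinusoidal drift below 0.02 Hz, with skin-conductance
#' responses at Poisson-like times (a 4 s dead time prevents unphysiological
#' pile-up; gap lengths are adjusted so the target rate is preserved) and a
#' bi-exponential kernel (1 s rise, 4 s decay) scaled to the requested
#' amplitude.
#'
#' @param scl_us tonic level target, microsiemens (scalar or per-phase).
#' @param scr_rate_per_min SCR event rate (scalar or per-phase, >= 0).
#' @param duration_s,phases as in [synth_ecg()].
#' @param scr_amplitude_us SCR peak amplitude, microsiemens.
#' @param drift_us slow-drift amplitude, microsiemens.
#' @param noise_us SD of additive measurement noise, microsiemens.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return an EDA [channel_signal()] with attribute `scr_times_s`.
#' @export
synth_eda <- function(scl_us, scr_rate_per_min, duration_s = NULL,
                      phases = NULL, scr_amplitude_us = 0.3, drift_us = 0.08,
                      noise_us = 0, fs = 500, seed = 1L) {
  if (is.null(phases)) {
    stopifnot(!is.null(duration_s))
    phases <- phase_annotation("baseline", 0, duration_s)
  }
  dur <- max(phases$end_s)
  scl_p <- phase_values(scl_us, phases)
  rate_p <- phase_values(scr_rate_per_min, phases)
  stopifnot(all(rate_p >= 0))
  n <- ceiling(dur * fs)
  # tonic at a 4 Hz working grid, Gaussian-smoothed across boundaries
  fg <- 4
  tg <- seq(0, dur, by = 1 / fg)
  lvl <- stats::approx(phases$start_s, scl_p, xout = pmin(tg, max(phases$start_s)),
                       method = "constant", rule = 2)$y
  ks <- 10 * fg   # 10 s Gaussian smoothing
  kern <- stats::dnorm(seq(-3 * ks, 3 * ks), 0, ks)
  kern <- kern / sum(kern)
  pad <- length(kern) %/% 2
  lvl_s <- stats::filter(c(rep(lvl[1], pad), lvl, rep(lvl[length(lvl)], pad)),
                         kern, sides = 2)
  lvl_s <- as.numeric(lvl_s[(pad + 1):(pad + length(lvl))])
  events <- with_seed(seed, {
    ev <- numeric(0)
    phi <- runif(1, 0, 2 * pi)
    for (p in seq_len(nrow(phases))) {
      r <- rate_p[p]
      if (r <= 0) next
      gap_mean <- 60 / r
      exp_mean <- max(gap_mean - 4, 0.5)
      t <- phases$start_s[p] + rexp(1, 1 / exp_mean)
      while (t < phases$end_s[p]) {
        ev <- c(ev, t)
        t <- t + 4 + rexp(1, 1 / exp_mean)
      }
    }
    list(ev = ev, phi = phi)
  })
  t_full <- (seq_len(n) - 1L) / fs
  x <- stats::approx(tg, lvl_s, xout = t_full, rule = 2)$y +
    drift_us * sin(2 * pi * 0.008 * t_full + events$phi)
  if (length(events$ev)) {
    tau <- seq(0, 20, by = 1 / fs)
    kernel <- exp(-tau / 4) - exp(-tau / 1)
    kernel <- scr_amplitude_us * kernel / max(kernel)
    for (et in events$ev) {
      i0 <- round(et * fs) + 1L
      idx <- seq(i0, min(i0 + length(kernel) - 1L, n))
      x[idx] <- x[idx] + kernel[seq_along(idx)]
    }
  }
  if (noise_us > 0)
    x <- x + with_seed(seed + 1L, rnorm(n, 0, noise_us))
  ch <- channel_signal("eda", x, fs)
  attr(ch, "scr_times_s") <- events$ev
  ch
}

#' Synthetic respiration channel
#'
#' Unit-amplitude sinusoidal thoracic-expansion trace at per-phase breathing
#' rates (phase-continuous across rate changes) plus Gaussian noise.
#'
#' @param resp_rate_bpm breaths per minute (scalar or per-phase).
#' @param duration_s,phases as in [synth_ecg()].
#' @param noise SD of additive noise (expansion units).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return a respiration [channel_signal()].
#' @export
synth_respiration <- function(resp_rate_bpm, duration_s = NULL, phases = NULL,
                              noise = 0, fs = 500, seed = 1L) {
  if (is.null(phases)) {
    stopifnot(!is.null(duration_s))
    phases <- phase_annotation("baseline", 0, duration_s)
  }
  dur <- max(phases$end_s)
  f_p <- phase_values(resp_rate_bpm, phases) / 60
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  f_t <- stats::approx(phases$start_s, f_p, xout = pmin(t, max(phases$start_s)),
                       method = "constant", rule = 2)$y
  phase_angle <- 2 * pi * cumsum(f_t) / fs
  x <- sin(phase_angle)
  if (noise > 0) x <- x + with_seed(seed, rnorm(n, 0, noise))
  channel_signal("respiration", x, fs)
}

#' Synthetic trapezius EMG channel
#'
#' Zero-mean Gaussian activity whose per-phase SD equals the target RMS
#' level (phase effects on muscle tension are weak in this paradigm, so the
#' defaults vary little across phases).
#'
#' @param rms_mv target RMS, mV (scalar or per-phase).
#' @param duration_s,phases as in [synth_ecg()].
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return an EMG [channel_signal()].
#' @export
synth_emg <- function(rms_mv, duration_s = NULL, phases = NULL, fs = 500,
                      seed = 1L) {
  if (is.null(phases)) {
    stopifnot(!is.null(duration_s))
    phases <- phase_annotation("baseline", 0, duration_s)
  }
  dur <- max(phases$end_s)
  rms_p <- phase_values(rms_mv, phases)
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  sd_t <- stats::approx(phases$start_s, rms_p, xout = pmin(t, max(phases$start_s)),
                        method = "constant", rule = 2)$y
  channel_signal("emg", with_seed(seed, rnorm(n)) * sd_t, fs)
}

#' Draw a synthetic baseline profile
#'
#' Cortisol is drawn from a phenotype-conditioned truncated log-normal
#' (salivary cortisol is right-skewed in practice) parameterized by the
#' mean/SD columns of [phenotype_specs()]; STAI from a truncated normal.
#' STAI totals are integers clipped to the instrument
#' range 20-80 and decomposed into 20 keyed item responses that sum to the
#' total. Final cortisol is drawn as a morning-decline fraction of baseline
#' (the session ends about 75 min after the stressor, by which time salivary
#' cortisol has fallen toward the printed 0.12 micrograms/dl level).
#'
#' @param phenotype a label or a one-row slice of [phenotype_specs()].
#' @param seed integer seed.
#' @param separation see [phenotype_specs()].
#' @param subject_id identifier for the emitted profile.
#' @return a [baseline_profile()].
#' @export
synth_baseline_profile <- function(phenotype, seed = 1L, separation = 1,
                                   subject_id = "synthetic") {
  if (is.character(phenotype)) {
    sp <- phenotype_specs(separation)
    phenotype <- sp[sp$label == phenotype, ]
    if (nrow(phenotype) != 1L) sr_stop("unknown phenotype label")
  }
  with_seed(seed, {
    cort <- rtlnorm(1, phenotype$cortisol_mean, phenotype$cortisol_sd,
                    lower = 0.02, upper = 2.5)
    stai <- round(rtnorm(1, phenotype$stai_mean, phenotype$stai_sd,
                         lower = 20, upper = 80))
    final <- cort * rtnorm(1, 0.32, 0.10, lower = 0.05, upper = 0.9)
    items <- rep(1L, 20L)
    add <- stai - 20L
    while (add > 0L) {
      room <- which(items < 4L)
      pick <- room[sample.int(length(room), min(add, length(room)))]
      items[pick] <- items[pick] + 1L
      add <- add - length(pick)
    }
    baseline_profile(subject_id, cort, stai, cortisol_final = final,
                     stai_items = items)
  })
}

# latent per-subject targets + channels for one subject
generate_subject <- function(subject_id, group, phenotype, config, seed) {
  phases <- config_phases(config)
  ns <- config$noise_scale
  sp <- phenotype_specs(config$separation)
  row <- if (group == "experimental") sp[sp$label == phenotype, ] else
    data.frame(label = NA_character_, hr_reactivity_pct = 0,
               hr_residual_pct = 0, scl_reactivity_pct = 0,
               scl_residual_pct = 0)
  lat <- with_seed(seed, {
    list(hr0 = rtnorm(1, 70, 6, 55, 90),
         scl0 = rtnorm(1, 6, 1.5, 2, 12),
         resp0 = rtnorm(1, 15, 1.5, 10, 22),
         rsa_amp = rtnorm(1, 6, 1.5, 2, 10),
         edr0 = rtnorm(1, 4, 1, 1.5, 8),
         wiggle = rnorm(14, 0, config$phase_wiggle_pct / 100 * ns))
  })
  mult <- function(react, resid) c(1, 1 + react / 100, rep(1 + resid / 100, 5))
  hr_t <- lat$hr0 * mult(row$hr_reactivity_pct, row$hr_residual_pct) *
    (1 + lat$wiggle[1:7])
  scl_t <- lat$scl0 * mult(row$scl_reactivity_pct, row$scl_residual_pct) *
    (1 + lat$wiggle[8:14])
  hr_t <- pmin(pmax(hr_t, 45), 175)
  edr_t <- lat$edr0 * mult(row$scl_reactivity_pct, row$scl_residual_pct)
  names(hr_t) <- names(scl_t) <- names(edr_t) <- phases$phase
  ecg <- synth_ecg(hr_t, phases = phases, rsa_amplitude_bpm = lat$rsa_amp,
                   resp_rate_bpm = lat$resp0,
                   rr_jitter_ms = config$rr_jitter_ms * ns,
                   noise_mv = config$ecg_noise_mv * ns,
                   fs = config$sampling_rate, seed = seed + 11L)
  eda <- synth_eda(scl_t, edr_t, phases = phases,
                   scr_amplitude_us = config$scr_amplitude_us,
                   drift_us = config$scl_drift_us * ns,
                   noise_us = config$eda_noise_us * ns,
                   fs = config$sampling_rate, seed = seed + 12L)
  resp <- synth_respiration(lat$resp0, phases = phases,
                            noise = config$resp_noise * ns,
                            fs = config$sampling_rate, seed = seed + 13L)
  emg_t <- setNames(0.05 * c(1, 1.08, rep(1.05, 5)), phases$phase)
  emg <- synth_emg(emg_t, phases = phases, fs = config$sampling_rate,
                   seed = seed + 14L)
  profile <- synth_baseline_profile(
    if (group == "experimental") phenotype else
      sample_phenotype_for_control(config, seed),
    seed = seed + 15L, separation = config$separation,
    subject_id = subject_id)
  missions <- with_seed(seed + 16L, {
    p_met <- c(0.92, 0.85, 0.78, 0.6, 0.8)
    mission_log(subject_id, 1:5,
                duration_s = round(config$scenario_s *
                                     rtnorm(5, 0.9, 0.12, 0.5, 1.3)),
                objectives_total = 5L,
                objectives_met = stats::rbinom(5, 5, p_met),
                times_shot = rpois(5, 0.25 * (1:5)),
                civilian_hits = stats::rbinom(5, 1, 0.05),
                par_time_s = config$scenario_s)
  })
  rec <- suppressWarnings(
    recording(subject_id, group, list(ecg, eda, resp, emg), phases))
  truth <- data.frame(subject_id = subject_id, group = group,
                      phenotype = if (group == "experimental") phenotype
                      else NA_character_,
                      rsa_amp_bpm = lat$rsa_amp, resp_rate_bpm = lat$resp0,
                      stringsAsFactors = FALSE)
  for (p in seq_len(nrow(phases))) {
    truth[[paste0("hr_", phases$phase[p])]] <- hr_t[p]
    truth[[paste0("scl_", phases$phase[p])]] <- scl_t[p]
    truth[[paste0("edr_", phases$phase[p])]] <- edr_t[p]
  }
  list(session = structure(list(recording = rec, profile = profile,
                                missions = missions),
                           class = "stress_session"),
       truth = truth)
}

# control subjects still get a baseline profile; draw their phenotype from
# the same mixture (it carries no latent reactivity for controls)
sample_phenotype_for_control <- function(config, seed) {
  with_seed(seed + 99L, {
    sample(names(config$phenotype_mix), 1, prob = config$phenotype_mix)
  })
}

# group and phenotype assignment for a config (deterministic under seed)
cohort_plan <- function(config) {
  n <- config$n_control + config$n_experimental
  ids <- sprintf("S%02d", seq_len(n))
  groups <- c(rep("control", config$n_control),
              rep("experimental", config$n_experimental))
  phen <- rep(NA_character_, n)
  exp_idx <- which(groups == "experimental")
  if (length(exp_idx)) {
    phen[exp_idx] <- with_seed(config$seed, {
      sample(names(config$phenotype_mix), length(exp_idx), replace = TRUE,
             prob = config$phenotype_mix)
    })
  }
  seeds <- derive_seeds(config$seed + 1L, n)
  data.frame(subject_id = ids, group = groups, phenotype = phen,
             seed = seeds, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' For every subject: a 7-phase session (baseline, TSST, five scenarios)
#' with all four raw channels, a baseline profile, and a mission log, plus
#' the per-subject ground truth (phenotype and per-phase latent targets) that
#' the recovery tests compare against. Experimental subjects' latent heart
#' rate and SCL follow their phenotype's reactivity/residual profile; control
#' subjects are flat near baseline. Identical config and seed give identical
#' output (byte-identical files when `out_dir` is used).
#'
#' Full-scale cohorts are large in memory (about 70 MB of raw samples per
#' subject at the protocol durations); use `out_dir` to stream subjects to
#' disk, or [cohort_features()] to reduce each subject to features without
#' retaining raw signals.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, each subject is written as
#'   a [write_session()] directory (`S01/`, `S02/`, ...) together with
#'   `ground_truth.tsv` and `cohort_config.tsv`, and raw signals are not
#'   retained in memory.
#' @return with `out_dir`: the directory path (invisibly). Otherwise a list
#'   with `sessions` (list of `stress_session`), `profiles`, `missions`,
#'   `truth` data.frames, and `plan`.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  plan <- cohort_plan(config)
  sessions <- list(); profiles <- list(); missions <- list(); truths <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (i in seq_len(nrow(plan))) {
    g <- generate_subject(plan$subject_id[i], plan$group[i],
                          plan$phenotype[i], config, plan$seed[i])
    profiles[[i]] <- g$session$profile
    missions[[i]] <- g$session$missions
    truths[[i]] <- g$truth
    if (is.null(out_dir)) {
      sessions[[plan$subject_id[i]]] <- g$session
    } else {
      write_session(g$session, file.path(out_dir, plan$subject_id[i]))
    }
  }
  truth <- do.call(rbind, truths)
  profiles <- do.call(rbind, profiles)
  missions <- do.call(rbind, missions)
  if (!is.null(out_dir)) {
    data.table::fwrite(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, na = "NA")
    cfg_df <- data.frame(key = names(unclass(config)),
                         value = vapply(unclass(config), function(v)
                           paste(format(v, digits = 15), collapse = ","),
                           character(1)))
    data.table::fwrite(cfg_df, file.path(out_dir, "cohort_config.tsv"),
                       sep = "\t", quote = FALSE)
    return(invisible(out_dir))
  }
  list(sessions = sessions, profiles = profiles, missions = missions,
       truth = truth, plan = plan)
}

#' Generate and reduce a cohort to features without retaining raw signals
#'
#' Streams the generator: each subject's session is synthesized, reduced with
#' [extract_features()], and discarded, keeping memory flat across cohort
#' size. This is the entry point for end-to-end recovery studies.
#'
#' @param config a [cohort_config()].
#' @param analysis an [analysis_config()].
#' @return list with `features` (all subjects), `profiles`, `missions`,
#'   `truth`, `plan`.
#' @export
cohort_features <- function(config = cohort_config(),
                            analysis = analysis_config()) {
  plan <- cohort_plan(config)
  feats <- list(); profiles <- list(); missions <- list(); truths <- list()
  for (i in seq_len(nrow(plan))) {
    g <- generate_subject(plan$subject_id[i], plan$group[i],
                          plan$phenotype[i], config, plan$seed[i])
    feats[[i]] <- suppressWarnings(extract_features(g$session, analysis))
    profiles[[i]] <- g$session$profile
    missions[[i]] <- g$session$missions
    truths[[i]] <- g$truth
    rm(g)
  }
  list(features = do.call(rbind, feats),
       profiles = do.call(rbind, profiles),
       missions = do.call(rbind, missions),
       truth = do.call(rbind, truths), plan = plan)
}

#' Generate synthetic baseline profiles only
#'
#' Fast path for classifier studies: draws phenotype labels from the mixture
#' and a (cortisol, STAI) profile per subject, skipping raw signals.
#'
#' @param n number of subjects.
#' @param config a [cohort_config()] (mixture, separation, seed).
#' @return `data.frame` with `subject_id`, `label`, `cortisol_baseline`,
#'   `stai_baseline`.
#' @export
synth_baseline_cohort <- function(n = 19L, config = cohort_config()) {
  labels <- with_seed(config$seed, {
    sample(names(config$phenotype_mix), n, replace = TRUE,
           prob = config$phenotype_mix)
  })
  seeds <- derive_seeds(config$seed + 2L, n)
  rows <- lapply(seq_len(n), function(i) {
    pr <- synth_baseline_profile(labels[i], seed = seeds[i],
                                 separation = config$separation,
                                 subject_id = sprintf("S%02d", i))
    data.frame(subject_id = pr$subject_id, label = labels[i],
               cortisol_baseline = pr$cortisol_baseline,
               stai_baseline = pr$stai_baseline, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
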