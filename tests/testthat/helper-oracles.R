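# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use direct per-sample arithmetic (no filters, no
# package helpers) so they stay independent of the implementation they check.

# beat series built directly from a known RR sequence
make_beats <- function(rr, t0 = 0) {
  times <- t0 + c(0, cumsum(rr))
  structure(list(r_peak_times_s = times, rr_intervals_s = rr,
                 rr_valid_mask = 60 / rr >= 40 & 60 / rr <= 180),
            class = "beat_series")
}

# respiratory cycle series with fixed boundaries
make_cycles <- function(boundaries) {
  structure(list(cycle_boundaries_s = boundaries,
                 rate_breaths_per_min = 60 / mean(diff(boundaries))),
            class = "resp_cycle_series")
}

# raw ECG rendered from explicit beat times (independent of synth_ecg)
render_ecg <- function(beat_times, duration_s, fs = 500) {
  n <- ceiling(duration_s * fs)
  x <- numeric(n)
  tau <- seq(-0.04, 0.04, by = 1 / fs)
  spike <- exp(-(tau / 0.008)^2)
  off <- which.max(spike) - 1L
  for (bt in beat_times) {
    i0 <- round(bt * fs) + 1L - off
    idx <- seq(i0, i0 + length(spike) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + spike[ok]
  }
  channel_signal("ecg", x, fs)
}

# brute-force block RMS: explicit loop, no matrix reshaping
brute_block_rms <- function(x, block) {
  nb <- length(x) %/% block
  vals <- numeric(nb)
  for (b in seq_len(nb)) {
    seg <- x[((b - 1) * block + 1):(b * block)]
    vals[b] <- sqrt(sum(seg^2) / block)
  }
  mean(vals)
}

# brute-force population SD in ms
brute_sdnn_ms <- function(rr) {
  m <- sum(rr) / length(rr)
  sqrt(sum((rr - m)^2) / length(rr)) * 1000
}

# two-phase (baseline + tsst) recording with all four channels
make_two_phase_recording <- function(hr = c(baseline = 70, tsst = 85),
                                     scl = c(baseline = 5, tsst = 6),
                                     seed = 1L) {
  ph <- phase_annotation(c("baseline", "tsst"), c(0, 300), c(300, 600))
  rec <- recording(
    "T01", "experimental",
    list(synth_ecg(hr, phases = ph, rsa_amplitude_bpm = 4,
                   resp_rate_bpm = 15, rr_jitter_ms = 10, seed = seed),
         synth_eda(scl, 4, phases = ph, seed = seed + 1L),
         synth_respiration(15, phases = ph, noise = 0.02, seed = seed + 2L),
         synth_emg(0.05, phases = ph, seed = seed + 3L)),
    ph)
  rec
}

# stress trajectory assembled directly from phase scores
make_trajectory <- function(scores, aggregate = "mean") {
  scen <- scores[grep("^scenario", names(scores))]
  agg <- switch(aggregate, mean = mean(scen), last = scen[[length(scen)]],
                max = max(scen))
  structure(list(subject_id = "T", score_by_phase = scores,
                 score_scenarios = agg,
                 pct_change_tsst = 100 * (scores[["tsst"]] - scores[["baseline"]]) /
                   scores[["baseline"]],
                 pct_change_scenarios = 100 * (agg - scores[["baseline"]]) /
                   scores[["baseline"]]),
            class = "stress_trajectory")
}
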