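# Internal helpers shared across modules.

PHASES <- c("baseline", "tsst", paste0("scenario", 1:5))
SCENARIO_PHASES <- paste0("scenario", 1:5)
CHANNEL_NAMES <- c("ecg", "eda", "respiration", "emg")
CHANNEL_UNITS <- c(ecg = "mV", eda = "uS", respiration = "au", emg = "mV")
RESILIENCE_LABELS <- c("resistant", "resilient", "recovery", "dysfunctional")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Stop with a short classed error used throughout the package
#' @noRd
sr_stop <- function(msg, class = "stressres_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Half-open sample slice: sample i (0-based) covers [i/fs, (i+1)/fs), so the
# window [start_s, end_s) holds samples i with i >= ceiling(start_s*fs) and
# i < ceiling(end_s*fs).
window_indices <- function(n, fs, start_s, end_s) {
  i0 <- ceiling(start_s * fs - 1e-9)
  i1 <- ceiling(end_s * fs - 1e-9) - 1
  i0 <- max(i0, 0L)
  i1 <- min(i1, n - 1L)
  if (i1 < i0) return(integer(0))
  seq.int(i0 + 1L, i1 + 1L)
}

# Decimate by non-overlapping block means (used ahead of sub-Hz filtering,
# where direct 500 Hz transfer-function filters are numerically fragile).
block_decimate <- function(x, block) {
  n <- (length(x) %/% block) * block
  if (n == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(n)], nrow = block))
}

# Population standard deviation (n denominator).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# Seeded RNG scoping: evaluate expr with a local seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive per-subject substream seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}
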