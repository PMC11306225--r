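# Beat delineation: PPG systolic peaks via an adaptive-threshold local-max
# search, ECG R-peaks via a squared-derivative energy detector (simplified
# Pan-Tompkins). Both are deterministic.

new_beat_set <- function(indices, fs, channel, refined = NULL) {
  structure(list(indices = as.integer(indices), fs = fs, channel = channel,
                 refined = refined %||% as.numeric(indices)),
            class = "beat_set")
}

# Parabolic sub-sample refinement of peak positions: fit a quadratic
# through the three samples around each peak. Worth ~1 sample of timing
# accuracy, which matters for pulse-arrival delays at 125 Hz.
refine_peaks <- function(x, idx) {
  refined <- as.numeric(idx)
  ok <- idx > 1L & idx < length(x)
  den <- x[idx[ok] - 1L] - 2 * x[idx[ok]] + x[idx[ok] + 1L]
  delta <- ifelse(abs(den) > 1e-12,
                  0.5 * (x[idx[ok] - 1L] - x[idx[ok] + 1L]) / den, 0)
  refined[ok] <- idx[ok] + clamp(delta, -0.5, 0.5)
  refined
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d %s beats at %g Hz\n",
              length(x$indices), x$channel, x$fs))
  invisible(x)
}

#' Detect PPG systolic peaks
#'
#' Local maxima above an adaptive threshold (rolling 75th percentile,
#' computed over ~2 s blocks and interpolated), with a minimum separation
#' of `refractory_s`; when two candidates fall within the refractory
#' interval the larger one wins.
#'
#' @param ppg Sample vector (band-passed PPG recommended).
#' @param fs Sampling rate, Hz.
#' @param refractory_s Minimum beat separation in seconds (default 0.33 s,
#'   i.e. at most ~180 bpm).
#' @param threshold_quantile Quantile of the rolling amplitude distribution
#'   used as the detection floor.
#' @return A `beat_set` with 1-based sample indices of the peaks; empty
#'   when fewer than one peak is found (flat lines yield no beats).
#' @export
detect_beats <- function(ppg, fs, refractory_s = 0.33, threshold_quantile = 0.75) {
  x <- ppg
  n <- length(x)
  if (n < 3L || !any(is.finite(x)) || pop_sd(x[is.finite(x)]) == 0)
    return(new_beat_set(integer(0), fs, "PPG"))
  x[!is.finite(x)] <- 0
  thr <- block_stat(x, round(2 * fs), function(v) quantile(v, threshold_quantile, names = FALSE))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr[cand]]
  keep_refractory(cand, x, round(refractory_s * fs), fs, "PPG")
}

#' Detect ECG R-peaks
#'
#' Squared first-difference energy with an adaptive block threshold marks
#' QRS regions; each region's R index is the local maximum of the raw
#' signal, and a refractory interval of `refractory_s` removes doubles.
#'
#' @param ecg Sample vector.
#' @param fs Sampling rate, Hz.
#' @param refractory_s Minimum R-R separation in seconds.
#' @return A `beat_set` of R-peak indices.
#' @export
detect_beats_ecg <- function(ecg, fs, refractory_s = 0.33) {
  x <- ecg
  n <- length(x)
  if (n < 3L || !any(is.finite(x)) || pop_sd(x[is.finite(x)]) == 0)
    return(new_beat_set(integer(0), fs, "ECG"))
  x[!is.finite(x)] <- 0
  energy <- c(0, diff(x))^2
  thr <- block_stat(energy, round(2 * fs),
                    function(v) quantile(v, 0.75, names = FALSE) + 0.2 * (max(v) - quantile(v, 0.75, names = FALSE)))
  hot <- energy > thr & energy > 1e-12
  cand <- which(hot)
  if (length(cand) == 0L) return(new_beat_set(integer(0), fs, "ECG"))
  # refine each hot sample to the nearest raw-signal local max within 60 ms
  w <- round(0.06 * fs)
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, 0L)
  keep_refractory(unique(ref), x, round(refractory_s * fs), fs, "ECG")
}

# Greedy refractory suppression: accept candidates in decreasing amplitude
# order, rejecting any within `gap` samples of an accepted peak.
keep_refractory <- function(cand, x, gap, fs, channel) {
  if (length(cand) == 0L) return(new_beat_set(integer(0), fs, channel))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || min(abs(kept - i)) >= gap) kept <- c(kept, i)
  }
  kept <- sort(kept)
  new_beat_set(kept, fs, channel, refined = refine_peaks(x, kept))
}

#' Restrict a beat set to a sample interval
#' @param beats A `beat_set`.
#' @param start 0-based start sample of the half-open interval.
#' @param len Interval length in samples.
#' @return A `beat_set` with indices inside `[start, start + len)`,
#'   re-expressed relative to the record (indices unchanged).
#' @export
beats_in_window <- function(beats, start, len) {
  keep <- beats$indices > start & beats$indices <= start + len
  new_beat_set(beats$indices[keep], beats$fs, beats$channel,
               refined = beats$refined[keep])
}
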