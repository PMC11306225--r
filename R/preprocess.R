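# Band-pass filtering, autocorrelation-based signal-quality scoring and
# label-range filtering, plus the sweep utilities that quantify how much
# data each setting throws away.

#' Preprocessing settings
#'
#' @param band_low,band_high Band-pass edges in Hz. Defaults 0.5 and 16 Hz,
#'   the edges conventionally used to denoise PPG.
#' @param autocorr_threshold Quality threshold in `[0, 1]` used by
#'   [filter_windows()]; sweeps typically cover `[0, 0.8]`.
#' @param lag_search Lag interval (s) searched for the autocorrelation
#'   peak; the default 0.33-2 s covers 30-180 bpm.
#' @return A `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.5, band_high = 16,
                              autocorr_threshold = 0.5,
                              lag_search = c(0.33, 2.0)) {
  if (band_low <= 0 || band_low >= band_high)
    stopf("need 0 < band_low < band_high")
  if (autocorr_threshold < 0 || autocorr_threshold > 1)
    stopf("autocorr_threshold must be in [0, 1]")
  structure(list(band_low = band_low, band_high = band_high,
                 autocorr_threshold = autocorr_threshold,
                 lag_search = lag_search),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' Cascaded 4th-order Butterworth high-pass and low-pass sections, each
#' applied forward-backward (`signal::filtfilt`), so the output has no
#' phase distortion and the same length as the input.
#'
#' @param values Sample vector.
#' @param fs Sampling rate, Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered samples.
#' @export
bandpass <- function(values, fs, cfg = preprocess_config()) {
  nyq <- fs / 2
  if (cfg$band_high >= nyq)
    stopf("band_high (%g Hz) must be below the Nyquist rate (%g Hz)", cfg$band_high, nyq)
  if (length(values) < 3 * fs / cfg$band_low)
    warnf("input shorter than ~3 cycles of band_low; edge effects likely")
  hp <- signal::butter(4, cfg$band_low / nyq, type = "high")
  lp <- signal::butter(4, cfg$band_high / nyq, type = "low")
  y <- signal::filtfilt(hp, values)
  as.numeric(signal::filtfilt(lp, y))
}

#' Band-pass every record of a cohort (PPG channel)
#' @param coh A `ppg_cohort`.
#' @param cfg A [preprocess_config()].
#' @return The cohort with filtered PPG channels.
#' @export
bandpass_cohort <- function(coh, cfg = preprocess_config()) {
  out <- lapply(coh, function(r) {
    r$channels$PPG <- bandpass(r$channels$PPG, r$fs, cfg)
    r
  })
  class(out) <- class(coh)
  out
}

#' Autocorrelation signal-quality score
#'
#' The score of a window is the maximum over physiologic lags of the
#' lagged self-correlation of the window (Pearson correlation between the
#' window and its lag-shifted copy, mean-removed per overlap segment). A
#' perfectly periodic window scores ~1, white noise scores near 0, and a
#' zero-variance window is defined to score 0. Lags beyond the available
#' window length are skipped.
#'
#' @param values Sample vector (one window), or a `window_set`.
#' @param fs Sampling rate, Hz (ignored when `values` is a `window_set`).
#' @param cfg A [preprocess_config()]; `lag_search` gives the lag interval.
#' @return A score in `[-1, 1]` (vector of scores for a `window_set`).
#' @export
autocorr_quality <- function(values, fs = NULL, cfg = preprocess_config()) {
  if (inherits(values, "window_set")) {
    ws <- values
    return(vapply(seq_len(n_windows(ws)), function(i)
      autocorr_quality(ws$values[i, ], ws$fs, cfg), 0.0))
  }
  x <- values
  n <- length(x)
  if (n < 4L || !all(is.finite(x)) || pop_sd(x) == 0) return(0)
  # lags beyond the search interval or leaving less than half the window
  # of overlap are skipped (short overlaps give meaningless correlations)
  max_lag <- min(round(cfg$lag_search[2] * fs), floor(n / 2))
  if (max_lag < round(cfg$lag_search[1] * fs)) return(0)
  lags <- seq.int(max(1L, round(cfg$lag_search[1] * fs)), max_lag)
  best <- -1
  for (l in lags) {
    a <- x[1:(n - l)]
    b <- x[(1 + l):n]
    if (sd(a) == 0 || sd(b) == 0) next
    r <- cor(a, b)
    if (r > best) best <- r
  }
  best
}

#' Filter report
#' @param n_in,n_kept Window counts before/after.
#' @param setting The filter setting applied.
#' @param n_unlabeled Windows excluded for missing labels (range filter).
#' @return A `filter_report` with `retention = n_kept / n_in`.
#' @export
filter_report <- function(n_in, n_kept, setting, n_unlabeled = 0L) {
  structure(list(n_in = n_in, n_kept = n_kept,
                 retention = if (n_in > 0) n_kept / n_in else NA_real_,
                 n_unlabeled = n_unlabeled, setting = setting),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d / %d windows (retention %.1f%%); setting: %s\n",
              x$n_kept, x$n_in, 100 * x$retention,
              paste(deparse(x$setting), collapse = "")))
  invisible(x)
}

#' Keep windows above an autocorrelation quality threshold
#'
#' @param ws A `window_set`.
#' @param cfg A [preprocess_config()]; `autocorr_threshold` is the cut.
#' @param scores Optional precomputed scores (to avoid recomputation in
#'   sweeps).
#' @return List with `windows` (the kept subset) and `report`
#'   (a [filter_report()]).
#' @export
filter_windows <- function(ws, cfg = preprocess_config(), scores = NULL) {
  if (is.null(scores)) scores <- autocorr_quality(ws, cfg = cfg)
  keep <- scores >= cfg$autocorr_threshold
  list(windows = ws[keep],
       report = filter_report(n_windows(ws), sum(keep),
                              setting = c(autocorr_threshold = cfg$autocorr_threshold)))
}

#' Retention across a sweep of quality thresholds
#'
#' @param ws A `window_set`.
#' @param thresholds Numeric vector of thresholds.
#' @param cfg A [preprocess_config()].
#' @return Data frame with columns `threshold`, `n_kept`, `retention`.
#' @export
quality_sweep <- function(ws, thresholds = seq(0, 0.8, by = 0.2),
                          cfg = preprocess_config()) {
  scores <- autocorr_quality(ws, cfg = cfg)
  data.frame(threshold = thresholds,
             n_kept = vapply(thresholds, function(th) sum(scores >= th), 0L),
             retention = vapply(thresholds, function(th) mean(scores >= th), 0.0))
}

#' Label-range filter settings
#'
#' @param sbp_min,sbp_max Inclusive SBP bounds in mmHg. The presets
#'   commonly seen in the literature are 65-200, 75-165 and 75-150.
#' @return A `range_filter_spec`.
#' @export
range_filter_spec <- function(sbp_min, sbp_max) {
  if (sbp_min >= sbp_max) stopf("need sbp_min < sbp_max")
  structure(list(sbp_min = sbp_min, sbp_max = sbp_max), class = "range_filter_spec")
}

#' Keep windows whose label lies inside a closed range
#'
#' Windows without a label for `target` are excluded and counted
#' separately in the report.
#'
#' @param ws A labeled `window_set`.
#' @param spec A [range_filter_spec()].
#' @param target Label column (default `"SBP"`).
#' @return List with `windows` and `report`.
#' @export
range_filter <- function(ws, spec, target = "SBP") {
  if (is.null(ws$labels) || !target %in% names(ws$labels))
    stopf("windows carry no '%s' labels", target)
  y <- ws$labels[[target]]
  labeled <- is.finite(y)
  keep <- labeled & y >= spec$sbp_min & y <= spec$sbp_max
  list(windows = ws[keep],
       report = filter_report(n_windows(ws), sum(keep),
                              setting = c(sbp_min = spec$sbp_min, sbp_max = spec$sbp_max),
                              n_unlabeled = sum(!labeled)))
}
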