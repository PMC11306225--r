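# The multi-valued-mapping checker: find window pairs that are close in
# input (waveform) space but far apart in label space, and report the
# fraction of windows with at least one such partner. A high fraction means
# the input-to-label map is ill-conditioned: no regression model, however
# expressive, can resolve labels the input does not distinguish.

#' Multi-valued-mapping search settings
#'
#' @param input_threshold Euclidean distance threshold on aligned,
#'   per-record min-max normalized windows. The default 1.0 over a
#'   250-sample window corresponds to a mean-squared per-sample threshold
#'   of 4e-3.
#' @param output_threshold Label-difference threshold in task units.
#'   Conventional defaults by task: 8 mmHg for SBP, 8 bpm for HR, 0.02 s
#'   for RWAT (see [default_output_threshold()]).
#' @param scope `"intra_patient"` (qualifying partners share the patient
#'   id) or `"inter_patient"` (partners come from different patients). All
#'   labeled windows form the denominator in both scopes.
#' @param max_lag_s Alignment search range in seconds (cross-correlation
#'   lag, default +/- 0.5 s).
#' @return An `mvmap_config`.
#' @export
mvmap_config <- function(input_threshold = 1.0, output_threshold = 8,
                         scope = c("intra_patient", "inter_patient"),
                         max_lag_s = 0.5) {
  scope <- match.arg(scope)
  if (input_threshold <= 0 || output_threshold <= 0)
    stopf("thresholds must be > 0")
  structure(list(input_threshold = input_threshold,
                 output_threshold = output_threshold,
                 scope = scope, max_lag_s = max_lag_s),
            class = "mvmap_config")
}

#' Conventional output thresholds by task
#' @param target One of `"SBP"`, `"HR"`, `"RWAT"`.
#' @return Threshold in task units (8 mmHg, 8 bpm, 0.02 s).
#' @export
default_output_threshold <- function(target) {
  switch(target, SBP = 8, HR = 8, RWAT = 0.02,
         stopf("no default output threshold for target '%s'", target))
}

#' Align two windows by circular cross-correlation
#'
#' Finds the lag in `[-max_lag_s, max_lag_s]` maximizing the normalized
#' cross-correlation of the mean-removed windows, searching lags in the
#' order 0, +1, -1, +2, -2, ... so ties break toward the smallest absolute
#' lag, and returns the second window circularly shifted by that lag.
#' Zero-variance inputs yield lag 0 with correlation defined as 0.
#'
#' @param x,y Equal-length sample vectors at the same rate.
#' @param fs Sampling rate, Hz.
#' @param max_lag_s Search range in seconds.
#' @return List with `lag` (samples), `aligned` (shifted `y`) and `corr`.
#' @export
align <- function(x, y, fs = CANONICAL_FS, max_lag_s = 0.5) {
  L <- length(x)
  if (length(y) != L) stopf("windows must have equal length")
  max_lag <- min(round(max_lag_s * fs), L - 1L)
  a <- x - mean(x)
  b <- y - mean(y)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    return(list(lag = 0L, aligned = y, corr = 0))
  lags <- c(0L, as.vector(rbind(seq_len(max_lag), -seq_len(max_lag))))
  best <- -Inf; best_lag <- 0L
  for (l in lags) {
    s <- sum(a * circ_shift(b, l))
    if (s > best) { best <- s; best_lag <- l }
  }
  list(lag = best_lag, aligned = circ_shift(y, best_lag), corr = best / (na * nb))
}

# Circular shift: out[t] = v[t - lag] (indices mod length).
circ_shift <- function(v, lag) {
  L <- length(v)
  v[((seq_len(L) - 1L - lag) %% L) + 1L]
}

#' Aligned Euclidean distance between two windows
#'
#' Aligns `y` to `x` with [align()] and returns the L2 norm of the
#' difference over all samples. Symmetric in practice up to alignment
#' tie-breaking. Windows are expected on a per-record min-max normalized
#' scale (see [normalize_windows()]); the conventional threshold of 1.0 is
#' only meaningful on a bounded scale.
#'
#' @param x,y Equal-length sample vectors.
#' @param fs Sampling rate, Hz.
#' @param cfg An [mvmap_config()] (for `max_lag_s`).
#' @return The aligned Euclidean distance.
#' @export
pair_distance <- function(x, y, fs = CANONICAL_FS, cfg = mvmap_config()) {
  if (length(x) != length(y)) stopf("windows must have equal length")
  al <- align(x, y, fs, cfg$max_lag_s)
  sqrt(sum((x - al$aligned)^2))
}

#' Min-max normalize windows per record
#'
#' Scales every window by its source record's value range so all samples
#' lie in `[0, 1]` while relative amplitude differences *within* a record
#' are preserved (normalizing per window would erase amplitude
#' information).
#'
#' @param ws A `window_set`.
#' @return `ws` with normalized values.
#' @export
normalize_windows <- function(ws) {
  key <- paste(ws$info$patient_id, ws$info$record_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    v <- ws$values[rows, , drop = FALSE]
    lo <- min(v); hi <- max(v)
    ws$values[rows, ] <- if (hi > lo) (v - lo) / (hi - lo) else 0
  }
  ws
}

#' Search for multi-valued mappings
#'
#' For every labeled window, looks for a qualifying partner: a window in
#' scope whose aligned distance is at most `input_threshold` and whose
#' label differs by at least `output_threshold`. The report counts windows
#' with at least one partner (not pairs). The scan is an exact O(n^2) pair
#' loop; the optional pre-screen skips pairs whose sorted-value distance (a
#' lower bound under any alignment shift) already exceeds the input
#' threshold and never changes the result.
#'
#' @param ws A labeled `window_set` (2-s non-overlapping windows by
#'   convention).
#' @param target Label column to test.
#' @param cfg An [mvmap_config()].
#' @param prescreen Use the lower-bound pre-screen (default `TRUE`).
#' @param normalize Per-record min-max normalize values first (default
#'   `TRUE`; set `FALSE` if `ws` is already normalized).
#' @return An `mvmap_report`: `n_windows`, `n_matched`, `match_fraction`
#'   (percent), `n_unlabeled`, and `pairs` (data frame with window indices,
#'   aligned distance, label difference and alignment lag).
#' @export
find_matches <- function(ws, target = "SBP", cfg = mvmap_config(),
                         prescreen = TRUE, normalize = TRUE) {
  if (is.null(ws$labels) || !target %in% names(ws$labels))
    stopf("windows carry no '%s' labels", target)
  y_all <- ws$labels[[target]]
  labeled <- is.finite(y_all)
  sub <- ws[labeled]
  if (normalize) sub <- normalize_windows(sub)
  pid <- as.integer(factor(sub$info$patient_id))
  max_lag <- min(round(cfg$max_lag_s * sub$fs), ncol(sub$values) - 1L)
  # shift-invariant magnitude spectra for the pre-screen lower bound
  spec <- t(Mod(stats::mvfft(t(sub$values)))) / sqrt(ncol(sub$values))
  res <- cpp_find_matches(sub$values, spec, sub$labels[[target]], pid,
                          cfg$scope == "intra_patient",
                          cfg$input_threshold, cfg$output_threshold,
                          max_lag, prescreen)
  pairs <- data.frame(i = res$i, j = res$j, distance = res$distance,
                      dlabel = res$dlabel, lag = res$lag)
  structure(list(
    n_windows = n_windows(sub),
    n_matched = sum(res$matched),
    match_fraction = 100 * sum(res$matched) / max(1L, n_windows(sub)),
    n_unlabeled = sum(!labeled),
    matched = res$matched,
    pairs = pairs,
    target = target, config = cfg
  ), class = "mvmap_report")
}

#' @export
print.mvmap_report <- function(x, ...) {
  cat(sprintf("<mvmap_report> %s, %s: %d / %d windows matched (%.2f%%), %d pairs\n",
              x$target, x$config$scope, x$n_matched, x$n_windows,
              x$match_fraction, nrow(x$pairs)))
  invisible(x)
}
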