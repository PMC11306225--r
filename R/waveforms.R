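#' Construct a signal record
#'
#' A `signal_record` holds the synchronously sampled channels of one
#' recording session for one patient: typically a PPG (photoplethysmogram,
#' arbitrary units), an ABP (arterial blood pressure, mmHg) and/or an ECG
#' (mV) channel sharing a common sampling rate.
#'
#' @param patient_id,record_id Identifiers; `(patient_id, record_id)` pairs
#'   are expected to be unique within a cohort.
#' @param channels Named list of numeric vectors of equal length. Canonical
#'   names are `"PPG"`, `"ABP"`, `"ECG"`.
#' @param fs Sampling rate in Hz (> 0), shared by all channels.
#' @param start_day Start time of the record on a per-patient clock, in days.
#'   Used by calibration-drift analyses; defaults to 0.
#' @param demographics Optional named list (age, height, weight).
#' @param posture Optional posture tag (e.g. `"rest"`, `"sitting"`).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(patient_id, record_id, channels, fs,
                          start_day = 0, demographics = NULL, posture = NULL) {
  if (!is.list(channels) || is.null(names(channels)) || length(channels) == 0L)
    stopf("`channels` must be a non-empty named list of numeric vectors")
  lens <- vapply(channels, length, 0L)
  if (length(unique(lens)) != 1L)
    stopf("all channels must share the same length (got %s)",
          paste(lens, collapse = ", "))
  if (!is.numeric(fs) || fs <= 0) stopf("`fs` must be > 0")
  structure(list(
    patient_id = as.character(patient_id),
    record_id = as.character(record_id),
    channels = lapply(channels, as.numeric),
    fs = as.numeric(fs),
    start_day = as.numeric(start_day),
    demographics = demographics,
    posture = posture
  ), class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf("<signal_record> patient %s record %s: %s; %g Hz, %.1f s\n",
              x$patient_id, x$record_id,
              paste(names(x$channels), collapse = "/"),
              x$fs, n / x$fs))
  invisible(x)
}

#' Record duration in seconds
#' @param record A `signal_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  length(record$channels[[1L]]) / record$fs
}

#' Bundle records into a cohort
#'
#' @param records List of `signal_record` objects with unique
#'   `(patient_id, record_id)` pairs.
#' @return An object of class `ppg_cohort` (a list of records).
#' @export
cohort <- function(records) {
  if (length(records) == 0L) stopf("a cohort needs at least one record")
  ids <- vapply(records, function(r) paste(r$patient_id, r$record_id, sep = ":"), "")
  if (anyDuplicated(ids)) stopf("duplicate (patient_id, record_id) pairs in cohort")
  structure(records, class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  pats <- unique(vapply(x, `[[`, "", "patient_id"))
  cat(sprintf("<ppg_cohort> %d records from %d patients\n",
              length(x), length(pats)))
  invisible(x)
}

#' Segmentation settings
#'
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds;
#'   must satisfy `0 <= overlap_s < window_s`.
#' @param channel Channel to segment (default `"PPG"`).
#' @return A `segmentation_spec`.
#' @export
segmentation_spec <- function(window_s, overlap_s = 0, channel = "PPG") {
  if (overlap_s < 0 || overlap_s >= window_s)
    stopf("need 0 <= overlap_s < window_s")
  structure(list(window_s = window_s, overlap_s = overlap_s, channel = channel),
            class = "segmentation_spec")
}

# Internal window-set constructor. A window_set stores window sample values
# as rows of a matrix plus provenance and label tables, which keeps the
# pairwise-distance and feature machinery vectorized.
new_window_set <- function(values, info, labels, fs, window_s, channel) {
  stopifnot(nrow(values) == nrow(info))
  structure(list(values = values, info = info, labels = labels,
                 fs = fs, window_s = window_s, channel = channel),
            class = "window_set")
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) nrow(ws$values)

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d samples) from channel %s, %g Hz\n",
              n_windows(x), x$window_s, ncol(x$values), x$channel, x$fs))
  if (!is.null(x$labels) && ncol(x$labels) > 0L)
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a window set
#' @param x A `window_set`.
#' @param i Row index (windows to keep).
#' @param ... Ignored.
#' @return A `window_set` with the selected windows.
#' @export
`[.window_set` <- function(x, i, ...) {
  new_window_set(x$values[i, , drop = FALSE],
                 x$info[i, , drop = FALSE],
                 if (is.null(x$labels)) NULL else x$labels[i, , drop = FALSE],
                 x$fs, x$window_s, x$channel)
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical fs/window/channel settings.
#' @return A combined `window_set`.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !inherits(parts[[1L]], "window_set"))
    parts <- parts[[1L]]
  parts <- Filter(function(p) !is.null(p) && n_windows(p) > 0L, parts)
  if (length(parts) == 0L) stopf("nothing to bind")
  ref <- parts[[1L]]
  vals <- do.call(rbind, lapply(parts, `[[`, "values"))
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  labs <- lapply(parts, `[[`, "labels")
  labels <- if (all(vapply(labs, is.null, TRUE))) NULL else {
    cols <- unique(unlist(lapply(labs, names)))
    do.call(rbind, lapply(seq_along(parts), function(j) {
      l <- labs[[j]]
      out <- as.data.frame(setNames(rep(list(rep(NA_real_, n_windows(parts[[j]]))), length(cols)), cols))
      if (!is.null(l)) out[names(l)] <- l
      out
    }))
  }
  rownames(info) <- NULL
  new_window_set(vals, info, labels, ref$fs, ref$window_s, ref$channel)
}

#' Cut a record into fixed-length windows
#'
#' Windows are half-open sample intervals `[start, start + len)` placed at a
#' stride of `window_s - overlap_s` seconds; a trailing partial window is
#' dropped. A record shorter than one window yields an empty set with a
#' warning, not an error.
#'
#' @param record A `signal_record`.
#' @param spec A `segmentation_spec` (or window length in seconds, for
#'   convenience).
#' @param overlap_s,channel Used only when `spec` is given as a number.
#' @return A `window_set`. With `overlap_s = 0` the windows tile
#'   `floor(duration / window_s)` windows without sharing samples.
#' @export
segment <- function(record, spec, overlap_s = 0, channel = "PPG") {
  if (is.numeric(spec)) spec <- segmentation_spec(spec, overlap_s, channel)
  if (!spec$channel %in% names(record$channels))
    stopf("record %s has no channel %s", record$record_id, spec$channel)
  fs <- record$fs
  x <- record$channels[[spec$channel]]
  len <- round(spec$window_s * fs)
  stride <- round((spec$window_s - spec$overlap_s) * fs)
  n <- length(x)
  if (n < len) {
    warnf("record %s (%.2f s) shorter than window (%g s); no windows emitted",
          record$record_id, n / fs, spec$window_s)
    starts <- integer(0)
  } else {
    starts <- seq(0L, n - len, by = stride)
  }
  vals <- if (length(starts)) {
    t(vapply(starts, function(s) x[(s + 1L):(s + len)], numeric(len)))
  } else {
    matrix(numeric(0), 0L, len)
  }
  info <- data.frame(
    patient_id = rep(record$patient_id, length(starts)),
    record_id = rep(record$record_id, length(starts)),
    start_index = as.integer(starts),
    start_day = record$start_day + starts / fs / 86400,
    stringsAsFactors = FALSE
  )
  new_window_set(vals, info, NULL, fs, spec$window_s, spec$channel)
}

#' Segment every record of a cohort
#' @param coh A `ppg_cohort`.
#' @param spec A `segmentation_spec`.
#' @return A combined `window_set`.
#' @export
segment_cohort <- function(coh, spec) {
  parts <- lapply(coh, function(r) segment(r, spec))
  parts <- Filter(function(p) n_windows(p) > 0L, parts)
  bind_windows(parts)
}

#' Derive window-level labels from co-recorded channels
#'
#' SBP is the mean of the ABP systolic-peak values whose peaks fall inside
#' the window; HR is 60 divided by the median inter-beat interval, taken
#' from ECG R-peaks when an ECG channel is present and from PPG systolic
#' peaks otherwise. Windows whose label-channel segment contains non-finite
#' samples, or in which no beats are detected, get `NA` and are flagged in
#' the returned set's `labels$flagged` attribute.
#'
#' @param record The `signal_record` the windows came from.
#' @param ws A `window_set` produced by [segment()] on `record`.
#' @param targets Character subset of `c("SBP", "HR")`.
#' @return `ws` with a `labels` data frame filled in.
#' @export
derive_labels <- function(record, ws, targets = c("SBP", "HR")) {
  targets <- match.arg(targets, c("SBP", "HR"), several.ok = TRUE)
  fs <- record$fs
  len <- ncol(ws$values)
  labels <- ws$labels
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n_windows(ws)))
  flagged <- rep(FALSE, n_windows(ws))

  if ("SBP" %in% targets) {
    if (!"ABP" %in% names(record$channels))
      stopf("SBP labels need an ABP channel")
    abp <- record$channels$ABP
    beats <- detect_beats(abp, fs)
    sbp <- rep(NA_real_, n_windows(ws))
    for (w in seq_len(n_windows(ws))) {
      s <- ws$info$start_index[w]
      seg_idx <- (s + 1L):(s + len)
      if (any(!is.finite(abp[seg_idx]))) { flagged[w] <- TRUE; next }
      in_w <- beats$indices[beats$indices > s & beats$indices <= s + len]
      if (length(in_w) == 0L) { flagged[w] <- TRUE; next }
      sbp[w] <- mean(abp[in_w])
    }
    labels$SBP <- sbp
  }

  if ("HR" %in% targets) {
    use_ecg <- "ECG" %in% names(record$channels)
    ch <- if (use_ecg) record$channels$ECG else record$channels$PPG
    beats <- if (use_ecg) detect_beats_ecg(ch, fs) else detect_beats(ch, fs)
    hr <- rep(NA_real_, n_windows(ws))
    for (w in seq_len(n_windows(ws))) {
      s <- ws$info$start_index[w]
      seg_idx <- (s + 1L):(s + len)
      if (any(!is.finite(ch[seg_idx]))) { flagged[w] <- TRUE; next }
      in_w <- beats$indices[beats$indices > s & beats$indices <= s + len]
      if (length(in_w) < 2L) { flagged[w] <- TRUE; next }
      hr[w] <- 60 / median(diff(in_w) / fs)
    }
    labels$HR <- hr
  }

  attr(labels, "flagged") <- flagged
  ws$labels <- labels
  ws
}

#' Attach labels from a ground-truth table
#'
#' Joins a table with columns `patient_id`, `record_id`, `start_index` and
#' target columns (as produced by [generate_cohort()]) onto a window set by
#' exact provenance match.
#'
#' @param ws A `window_set`.
#' @param truth A data frame of per-window ground truth.
#' @param targets Named character vector mapping label names to truth
#'   columns, e.g. `c(SBP = "sbp", HR = "hr", RWAT = "rwat")`.
#' @return `ws` with labels attached.
#' @export
attach_labels <- function(ws, truth,
                          targets = c(SBP = "sbp", HR = "hr", RWAT = "rwat")) {
  key_ws <- paste(ws$info$patient_id, ws$info$record_id, ws$info$start_index)
  key_tr <- paste(truth$patient_id, truth$record_id, truth$start_index)
  idx <- match(key_ws, key_tr)
  labels <- ws$labels
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n_windows(ws)))
  for (nm in names(targets)) {
    col <- targets[[nm]]
    if (col %in% names(truth)) labels[[nm]] <- truth[[col]][idx]
  }
  ws$labels <- labels
  ws
}

#' Export a window label table as CSV
#'
#' Writes one row per window with provenance and label columns.
#'
#' @param ws A labeled `window_set`.
#' @param path Output file.
#' @return The data frame written, invisibly.
#' @export
write_window_table <- function(ws, path) {
  df <- cbind(ws$info, ws$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
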