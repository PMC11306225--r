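# Handcrafted pulse-wave features: heart rate, SDNN heart-rate
# variability, a composite signal-quality score, the normalized systolic
# ramp (dp/dt), and ECG-to-PPG pulse-arrival timing, plus subject-baseline
# deltas and rolling fluctuation (std.) columns.

#' Heart rate from a beat set
#'
#' 60 divided by the median inter-beat interval.
#'
#' @param beats A `beat_set` with at least 2 beats.
#' @return Heart rate in bpm, or `NA` with fewer than 2 beats.
#' @export
heart_rate <- function(beats) {
  if (length(beats$indices) < 2L) return(NA_real_)
  60 / median(diff(beats$refined) / beats$fs)
}

#' SDNN heart-rate variability
#'
#' Standard deviation (population form) of the normal-to-normal inter-beat
#' intervals. When the beats span at least `subdiv_s` seconds, the span is
#' cut into consecutive `subdiv_s` subdivisions and the mean of the
#' per-subdivision SDs is returned.
#'
#' @param beats A `beat_set` with at least 3 beats.
#' @param subdiv_s Subdivision length in seconds (default 60).
#' @return SDNN in seconds, or `NA` with fewer than 3 beats.
#' @export
sdnn <- function(beats, subdiv_s = 60) {
  if (length(beats$indices) < 3L) return(NA_real_)
  t <- beats$refined / beats$fs
  ibi <- diff(t)
  span <- t[length(t)] - t[1L]
  if (span < subdiv_s) return(pop_sd(ibi))
  bins <- floor((t[-length(t)] - t[1L]) / subdiv_s)
  sds <- tapply(ibi, bins, function(v) if (length(v) >= 2L) pop_sd(v) else NA_real_)
  mean(sds, na.rm = TRUE)
}

#' Composite signal-quality score
#'
#' Mean of up to three clamped components: (a) the autocorrelation quality
#' score clipped to `[0, 1]`; (b) the fraction of samples not inside
#' dropout/clipping runs (runs of constant value lasting >= 80 ms); (c) the
#' mean pairwise correlation of per-beat templates (each beat resampled to
#' a fixed length), clipped to `[0, 1]`. Components whose preconditions
#' fail are excluded from the mean; fully degenerate windows score 0.
#'
#' @param values Window sample vector.
#' @param fs Sampling rate, Hz.
#' @param cfg A [preprocess_config()] (for the autocorrelation component).
#' @param beats Optional precomputed `beat_set` local to `values`.
#' @return A score in `[0, 1]`.
#' @export
quality_score <- function(values, fs, cfg = preprocess_config(), beats = NULL) {
  x <- values
  n <- length(x)
  if (n < 4L || !any(is.finite(x))) return(0)
  comp <- c(a = clamp(autocorr_quality(x, fs, cfg), 0, 1),
            b = 1 - flat_run_fraction(x, fs),
            c = NA_real_)
  if (is.null(beats)) beats <- detect_beats(x, fs)
  tpl <- beat_templates(x, beats$indices, 50L)
  if (!is.null(tpl) && nrow(tpl) >= 2L) {
    cm <- suppressWarnings(cor(t(tpl)))
    comp["c"] <- clamp(mean(cm[upper.tri(cm)], na.rm = TRUE), 0, 1)
  }
  if (pop_sd(x[is.finite(x)]) == 0) return(0)
  mean(comp, na.rm = TRUE)
}

# Fraction of samples sitting in constant-value runs of >= min_s seconds
# (dropouts, railed/clipped segments).
flat_run_fraction <- function(x, fs, min_s = 0.08) {
  n <- length(x)
  flat <- c(FALSE, abs(diff(x)) < 1e-12)
  r <- rle(flat)
  min_len <- max(2L, round(min_s * fs))
  bad <- r$values & (r$lengths >= min_len - 1L)
  if (!any(bad)) return(0)
  # a run of k TRUE diffs spans k + 1 samples
  sum(r$lengths[bad] + 1L) / n
}

# Resample each beat-to-beat segment to `len` points; rows are templates.
beat_templates <- function(x, peak_idx, len = 50L) {
  if (length(peak_idx) < 3L) return(NULL)
  segs <- lapply(seq_len(length(peak_idx) - 1L), function(k) {
    seg <- x[peak_idx[k]:peak_idx[k + 1L]]
    if (length(seg) < 4L) return(NULL)
    approx(seq_along(seg), seg, n = len)$y
  })
  segs <- Filter(Negate(is.null), segs)
  if (length(segs) < 2L) return(NULL)
  do.call(rbind, segs)
}

#' Normalized systolic ramp (dp/dt)
#'
#' For each complete beat (a systolic peak with an identifiable foot, the
#' minimum between it and the preceding peak), the ramp is
#' `(peak value - foot value) / (peak time - foot time)`, multiplied by the
#' beat duration so the feature is expressed per beat-fraction rather than
#' per second. The feature is the mean over complete beats.
#'
#' @param values Window sample vector.
#' @param beats A `beat_set` with indices local to `values`.
#' @param fs Sampling rate, Hz.
#' @param onset_frac Fraction of the valley-to-peak range defining the
#'   upstroke onset (foot) sample.
#' @return Mean normalized ramp, or `NA` when no complete beat exists.
#' @export
systolic_ramp <- function(values, beats, fs, onset_frac = 0.1) {
  p <- beats$indices
  if (length(p) < 2L) return(NA_real_)
  ramps <- numeric(0)
  for (k in 2:length(p)) {
    seg <- values[p[k - 1L]:p[k]]
    v_min <- min(seg)
    # foot: the last sample before the peak still within onset_frac of the
    # valley-to-peak range (the upstroke onset). For a linear rise this
    # leaves the measured slope exactly equal to the true rise slope.
    thresh <- v_min + onset_frac * (seg[length(seg)] - v_min)
    below <- which(seg[-length(seg)] <= thresh)
    if (length(below) == 0L) next
    foot_rel <- max(below)
    foot <- p[k - 1L] + foot_rel - 1L
    if (foot >= p[k]) next
    dt <- (p[k] - foot) / fs
    duration <- (p[k] - p[k - 1L]) / fs
    ramps <- c(ramps, (values[p[k]] - values[foot]) / dt * duration)
  }
  if (length(ramps) == 0L) return(NA_real_)
  mean(ramps)
}

#' Pulse-arrival time from ECG R-peak to PPG systolic peak
#'
#' For every PPG systolic peak with a preceding R-peak, the delay to the
#' nearest preceding R-peak; the feature is the median delay. PPG beats
#' with no preceding R-peak are dropped; if none remain the feature is
#' missing.
#'
#' @param ecg_beats,ppg_beats `beat_set`s on a common sample clock.
#' @return Median delay in seconds, or `NA`.
#' @export
rpat <- function(ecg_beats, ppg_beats) {
  if (length(ecg_beats$indices) == 0L || length(ppg_beats$indices) == 0L)
    return(NA_real_)
  delays <- vapply(ppg_beats$refined, function(p) {
    prev <- ecg_beats$refined[ecg_beats$refined < p]
    if (length(prev) == 0L) return(NA_real_)
    (p - max(prev)) / ppg_beats$fs
  }, 0.0)
  delays <- delays[is.finite(delays)]
  if (length(delays) == 0L) return(NA_real_)
  median(delays)
}

#' Extract the handcrafted feature table for one record
#'
#' Band-passes the PPG channel, delineates beats once at record level, and
#' computes per-window features: `HR` (bpm), `SDNN` (s), `Quality`
#' (`[0,1]`), `dpdt` (normalized systolic ramp) and, when an ECG channel is
#' present, `rPAT` (s) and `invPAT` (1/s). The HR source channel (ECG when
#' present and trusted, else PPG) is recorded per row.
#'
#' @param record A `signal_record` with a PPG channel.
#' @param spec A [segmentation_spec()] for the feature windows.
#' @param cfg A [preprocess_config()].
#' @param use_ecg Use the ECG channel for heart rate and rPAT when present
#'   (set `FALSE` for records whose ECG clock is not trustworthy).
#' @return A data frame, one row per window, with provenance columns.
#' @export
extract_features <- function(record, spec, cfg = preprocess_config(),
                             use_ecg = TRUE) {
  fs <- record$fs
  ppg_f <- bandpass(record$channels$PPG, fs, cfg)
  ppg_beats <- detect_beats(ppg_f, fs)
  has_ecg <- use_ecg && "ECG" %in% names(record$channels)
  ecg_beats <- if (has_ecg) detect_beats_ecg(record$channels$ECG, fs) else NULL

  ws <- segment(record, spec)
  len <- ncol(ws$values)
  nw <- n_windows(ws)
  out <- ws$info
  out$HR <- out$SDNN <- out$Quality <- out$dpdt <- rep(NA_real_, nw)
  out$rPAT <- out$invPAT <- rep(NA_real_, nw)
  out$hr_source <- rep(if (has_ecg) "ECG" else "PPG", nw)
  for (w in seq_len(nw)) {
    s <- ws$info$start_index[w]
    pb <- beats_in_window(ppg_beats, s, len)
    hr_beats <- if (has_ecg) beats_in_window(ecg_beats, s, len) else pb
    out$HR[w] <- heart_rate(hr_beats)
    out$SDNN[w] <- sdnn(hr_beats)
    local_beats <- new_beat_set(pb$indices - s, fs, "PPG")
    seg_vals <- ppg_f[(s + 1L):(s + len)]
    out$Quality[w] <- quality_score(seg_vals, fs, cfg, beats = local_beats)
    out$dpdt[w] <- systolic_ramp(seg_vals, local_beats, fs)
    if (has_ecg) {
      eb <- beats_in_window(ecg_beats, max(0L, s - round(0.6 * fs)), len + round(0.6 * fs))
      out$rPAT[w] <- rpat(eb, pb)
      out$invPAT[w] <- ifelse(is.finite(out$rPAT[w]) && out$rPAT[w] > 0,
                              1 / out$rPAT[w], NA_real_)
    }
  }
  out
}

#' Extract features for every record of a cohort
#' @param coh A `ppg_cohort`.
#' @param spec A [segmentation_spec()].
#' @param cfg A [preprocess_config()].
#' @param use_ecg Passed to [extract_features()].
#' @return A combined data frame.
#' @export
extract_features_cohort <- function(coh, spec, cfg = preprocess_config(),
                                    use_ecg = TRUE) {
  do.call(rbind, lapply(coh, extract_features, spec = spec, cfg = cfg,
                        use_ecg = use_ecg))
}

#' Subject-baseline deltas and rolling fluctuation columns
#'
#' Adds `d.<f>` columns (feature minus the subject's baseline value, the
#' mean over that subject's designated baseline rows) and `std.<f>` columns
#' (SD of the feature over consecutive windows spanning `period_s` within a
#' record). Subjects without baseline rows get `NA` delta columns.
#'
#' @param table Feature data frame from [extract_features_cohort()].
#' @param baseline Logical vector marking the baseline rows of `table`
#'   (e.g. the at-rest posture record).
#' @param features Feature columns to process.
#' @param period_s Fluctuation period in seconds.
#' @return `table` with the added columns.
#' @export
delta_and_std_features <- function(table, baseline,
                                   features = c("HR", "SDNN", "dpdt", "rPAT"),
                                   period_s = 60) {
  features <- intersect(features, names(table))
  for (f in features) {
    base_vals <- tapply(table[[f]][baseline], table$patient_id[baseline],
                        mean, na.rm = TRUE)
    ref <- base_vals[as.character(table$patient_id)]
    table[[paste0("d.", f)]] <- table[[f]] - as.numeric(ref)
    key <- paste(table$patient_id, table$record_id)
    # group consecutive windows of a record into period_s chunks
    std_col <- rep(NA_real_, nrow(table))
    for (k in unique(key)) {
      rows <- which(key == k)
      rows <- rows[order(table$start_index[rows])]
      t0 <- table$start_index[rows]
      grp <- floor((t0 - t0[1L]) / (period_s * guess_fs(table, rows)))
      vals <- tapply(table[[f]][rows], grp, function(v) {
        v <- v[is.finite(v)]
        if (length(v) >= 2L) pop_sd(v) else NA_real_
      })
      std_col[rows] <- as.numeric(vals[as.character(grp)])
    }
    table[[paste0("std.", f)]] <- std_col
  }
  table
}

# start_index columns are in samples; infer fs from the provenance if
# present, defaulting to the canonical 125 Hz.
guess_fs <- function(table, rows) {
  if (!is.null(attr(table, "fs"))) return(attr(table, "fs"))
  CANONICAL_FS
}
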