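# Synthetic multi-patient PPG/ABP/ECG cohorts with controllable
# conditioning. The generator's job is to emulate the statistical structure
# the audit tools probe: slowly varying SBP within a record, per-patient
# baselines, an optional PPG-invisible SBP component (planted
# ill-conditioning), slow per-patient drift for calibration analyses, and
# MIMIC-style artifacts.

#' Noise / artifact settings for synthetic PPG
#'
#' @param baseline_wander_amp Amplitude of sub-0.5 Hz sinusoidal baseline
#'   wander, as a fraction of the pulse amplitude.
#' @param hf_noise_sd SD of additive white noise, as a fraction of the pulse
#'   amplitude.
#' @param dropout_rate Zeroed-gap events per minute.
#' @param amplitude_jump_rate Step changes in amplitude per minute.
#' @return A `noise_config`.
#' @export
noise_config <- function(baseline_wander_amp = 0, hf_noise_sd = 0,
                         dropout_rate = 0, amplitude_jump_rate = 0) {
  vals <- c(baseline_wander_amp, hf_noise_sd, dropout_rate, amplitude_jump_rate)
  if (any(vals < 0)) stopf("noise settings must be >= 0")
  structure(list(baseline_wander_amp = baseline_wander_amp,
                 hf_noise_sd = hf_noise_sd,
                 dropout_rate = dropout_rate,
                 amplitude_jump_rate = amplitude_jump_rate),
            class = "noise_config")
}

#' Scenario settings for the synthetic cohort generator
#'
#' Per patient, a baseline SBP is drawn uniformly in `sbp_baseline_range`
#' and a drift rate from `N(0, drift_per_day^2)`. Within a record, the
#' PPG-visible SBP component follows `baseline + AR(1)` (coefficient
#' `ar_coef` per window step, stationary SD `ar_sd`). True SBP adds the
#' drift term and, when `conditioning = "ill"`, a latent component drawn
#' i.i.d. per window from `N(0, latent_sd^2)` that moves blood pressure
#' without moving the waveform. Pulse morphology (reflected-wave timing)
#' tracks only the visible component, so `latent_sd` is a direct dial on
#' how multi-valued the PPG-to-SBP mapping is.
#'
#' @param n_patients,records_per_patient,record_s,fs Cohort shape.
#' @param hr_range Per-record heart-rate centres are drawn in this range (bpm).
#' @param sbp_baseline_range Per-patient SBP baselines (mmHg).
#' @param conditioning `"well"` or `"ill"`.
#' @param latent_sd SD (mmHg) of the PPG-invisible SBP component (used in
#'   `"ill"` mode).
#' @param drift_per_day SD (mmHg/day) of the per-patient slow drift rate;
#'   the drift is PPG-invisible, emulating BP change from factors a
#'   waveform cannot see.
#' @param rwat_range Reflected-wave arrival times (s).
#' @param pat_s Pulse-arrival delay from ECG R-peak to PPG systolic peak (s).
#' @param pulse_pressure SBP minus DBP for the rendered ABP channel (mmHg).
#' @param record_interval_days Spacing of a patient's records in days.
#' @param window_s Ground-truth bookkeeping window (s).
#' @param ar_coef,ar_sd AR(1) coefficient per window step and stationary SD
#'   (mmHg) of the within-record SBP fluctuation.
#' @param hr_wander_sd Within-record heart-rate wander SD (bpm).
#' @param amp_range Per-patient PPG pulse amplitudes (arbitrary units).
#' @param noise A [noise_config()] applied to every record's PPG channel.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(n_patients = 5, records_per_patient = 2,
                            record_s = 360, fs = 125,
                            hr_range = c(60, 100),
                            sbp_baseline_range = c(100, 145),
                            conditioning = c("well", "ill"),
                            latent_sd = 0, drift_per_day = 0,
                            rwat_range = c(0.12, 0.30), pat_s = 0.20,
                            pulse_pressure = 40,
                            record_interval_days = 1, window_s = 2,
                            ar_coef = 0.99, ar_sd = 2, hr_wander_sd = 1.5,
                            amp_range = c(0.8, 1.2),
                            noise = noise_config(), seed = 1) {
  conditioning <- match.arg(conditioning)
  if (fs <= 0) stopf("fs must be > 0")
  if (latent_sd < 0) stopf("latent_sd must be >= 0")
  if (diff(range(hr_range)) < 0 || diff(range(sbp_baseline_range)) < 0)
    stopf("ranges must be non-empty")
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate one synthetic PPG beat
#'
#' A beat of duration `60/hr` seconds modelled as a systolic Gaussian bump
#' plus a smaller reflected bump delayed by `rwat`, scaled so the global
#' maximum equals `amp`. Values are non-negative and the construction is
#' deterministic.
#'
#' @param hr Heart rate in bpm (30-220).
#' @param rwat Reflected-wave arrival time in seconds; must be positive and
#'   smaller than the beat period `60/hr`.
#' @param amp Peak amplitude (arbitrary units).
#' @param fs Sampling rate, Hz.
#' @param sys_frac Position of the systolic peak as a fraction of the beat.
#' @param sys_width_s,refl_width_s Gaussian widths (s).
#' @param refl_frac Reflected bump amplitude relative to the systolic bump.
#' @return Numeric vector of `round(fs * 60/hr)` samples.
#' @export
generate_beat <- function(hr, rwat, amp = 1, fs = 125,
                          sys_frac = 0.25, sys_width_s = 0.045,
                          refl_width_s = 0.07, refl_frac = 0.35) {
  if (hr < 30 || hr > 220) stopf("hr out of range [30, 220]: %g", hr)
  period <- 60 / hr
  if (rwat <= 0 || rwat >= period)
    stopf("rwat (%.3f s) must lie in (0, beat period = %.3f s)", rwat, period)
  n <- round(fs * period)
  t <- (seq_len(n) - 1L) / fs
  t_sys <- sys_frac * period
  y <- exp(-(t - t_sys)^2 / (2 * sys_width_s^2)) +
    refl_frac * exp(-(t - t_sys - rwat)^2 / (2 * refl_width_s^2))
  y * (amp / max(y))
}

#' Generate a synthetic cohort with ground truth
#'
#' Renders PPG, ABP and ECG channels for every record of a
#' [scenario_config()] and returns per-window ground truth. The ABP channel
#' is rendered so its systolic peaks equal the true SBP of the window the
#' peak falls in; ECG R-waves precede each PPG systolic peak by the
#' configured pulse-arrival delay.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `cohort` (a [cohort()]) and `truth` (a data
#'   frame with one row per ground-truth window: provenance, window time,
#'   `sbp`, `sbp_visible`, `latent`, `hr`, `rwat`, `pat`, `drift_rate`,
#'   `day`).
#' @export
generate_cohort <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    records <- list()
    truth <- list()
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%02d", p)
      baseline <- runif(1, cfg$sbp_baseline_range[1], cfg$sbp_baseline_range[2])
      drift_rate <- if (cfg$drift_per_day > 0) rnorm(1, 0, cfg$drift_per_day) else 0
      amp <- runif(1, cfg$amp_range[1], cfg$amp_range[2])
      # resting heart rate is a patient trait; records jitter around it
      hr_patient <- runif(1, cfg$hr_range[1], cfg$hr_range[2])
      for (r in seq_len(cfg$records_per_patient)) {
        rid <- sprintf("R%02d", r)
        start_day <- (r - 1) * cfg$record_interval_days
        rec <- render_record(cfg, pid, rid, baseline, drift_rate, amp,
                             hr_patient, start_day)
        rec$record$channels$PPG <-
          inject_artifacts_values(rec$record$channels$PPG, cfg$noise, cfg$fs)
        records[[length(records) + 1L]] <- rec$record
        truth[[length(truth) + 1L]] <- rec$truth
      }
    }
    list(cohort = cohort(records), truth = do.call(rbind, truth))
  })
}

# Render one record: per-window SBP processes, then beat-by-beat waveforms.
render_record <- function(cfg, pid, rid, baseline, drift_rate, amp,
                          hr_patient, start_day) {
  fs <- cfg$fs
  n_win <- floor(cfg$record_s / cfg$window_s)
  n_samp <- round(cfg$record_s * fs)
  win_len <- round(cfg$window_s * fs)

  # AR(1) fluctuation of the PPG-visible SBP component, one step per window.
  innov_sd <- cfg$ar_sd * sqrt(1 - cfg$ar_coef^2)
  ar <- numeric(n_win)
  ar[1L] <- rnorm(1, 0, cfg$ar_sd)
  for (w in seq_len(n_win)[-1L]) ar[w] <- cfg$ar_coef * ar[w - 1L] + rnorm(1, 0, innov_sd)

  sbp_visible <- baseline + ar
  latent <- if (cfg$conditioning == "ill" && cfg$latent_sd > 0) {
    rnorm(n_win, 0, cfg$latent_sd)
  } else rep(0, n_win)
  t_win <- (seq_len(n_win) - 1L) * cfg$window_s
  day <- start_day + t_win / 86400
  drift <- drift_rate * day
  sbp <- sbp_visible + drift + latent

  # Reflected-wave timing tracks the visible SBP component (higher pressure,
  # stiffer vessels, earlier reflection); heart rate wanders independently.
  vis_lo <- cfg$sbp_baseline_range[1] - 3 * cfg$ar_sd
  vis_hi <- cfg$sbp_baseline_range[2] + 3 * cfg$ar_sd
  frac <- clamp((sbp_visible - vis_lo) / (vis_hi - vis_lo), 0, 1)
  rwat <- cfg$rwat_range[2] - frac * diff(cfg$rwat_range)
  # higher pressure, steeper systolic upstroke: the dp/dt feature carrier
  sys_w <- 0.055 - 0.025 * frac

  hr0 <- clamp(hr_patient + rnorm(1, 0, 2), cfg$hr_range[1], cfg$hr_range[2])
  hr <- numeric(n_win)
  hr[1L] <- hr0
  for (w in seq_len(n_win)[-1L])
    hr[w] <- clamp(0.95 * (hr[w - 1L] - hr0) + hr0 + rnorm(1, 0, cfg$hr_wander_sd *
                     sqrt(1 - 0.95^2)), cfg$hr_range[1], cfg$hr_range[2])

  ppg <- numeric(n_samp)
  abp <- numeric(n_samp)
  ecg <- numeric(n_samp)
  dbp_of <- function(w) sbp[w] - cfg$pulse_pressure
  abp[] <- NA_real_  # overwritten beat by beat below

  t_beat <- runif(1, 0, 0.2)  # phase offset of the first beat
  while (TRUE) {
    w <- min(floor(t_beat / cfg$window_s) + 1L, n_win)
    period <- 60 / hr[w]
    t_peak <- t_beat + 0.25 * period
    if (t_beat >= cfg$record_s) break
    shape <- generate_beat(hr[w], rwat[w], amp = 1, fs = fs,
                           sys_width_s = sys_w[w])
    idx0 <- round(t_beat * fs)
    if (idx0 + 1L > n_samp) break
    idx <- (idx0 + 1L):min(idx0 + length(shape), n_samp)
    seg <- shape[seq_along(idx)]
    ppg[idx] <- pmax(ppg[idx], amp * seg)
    wp <- min(floor(t_peak / cfg$window_s) + 1L, n_win)
    abp[idx] <- ifelse(is.na(abp[idx]), dbp_of(wp) + cfg$pulse_pressure * seg,
                       pmax(abp[idx], dbp_of(wp) + cfg$pulse_pressure * seg))
    # impulse-like R-wave preceding the systolic peak by the arrival delay
    # (sample i holds time (i-1)/fs, matching the PPG rendering)
    r_idx <- round((t_peak - cfg$pat_s) * fs) + 1L
    if (r_idx >= 2L && r_idx < n_samp) {
      spread <- -2:2
      tri <- c(0.2, 0.6, 1, 0.6, 0.2)
      ok <- r_idx + spread >= 1L & r_idx + spread <= n_samp
      ecg[r_idx + spread[ok]] <- pmax(ecg[r_idx + spread[ok]], tri[ok])
    }
    t_beat <- t_beat + period
  }
  abp[is.na(abp)] <- dbp_of(1L)

  rec <- signal_record(pid, rid,
                       channels = list(PPG = ppg, ABP = abp, ECG = ecg),
                       fs = fs, start_day = start_day)
  tr <- data.frame(
    patient_id = pid, record_id = rid,
    start_index = as.integer((seq_len(n_win) - 1L) * win_len),
    t_s = t_win, day = day,
    sbp = sbp, sbp_visible = sbp_visible, latent = latent,
    hr = hr, rwat = rwat, pat = cfg$pat_s, drift_rate = drift_rate,
    stringsAsFactors = FALSE
  )
  list(record = rec, truth = tr)
}

#' Inject MIMIC-style artifacts into a record's PPG channel
#'
#' Adds sub-0.5 Hz sinusoidal baseline wander, white noise, zeroed dropout
#' gaps and step changes in amplitude at Poisson event times. The input
#' record is not modified.
#'
#' @param record A `signal_record` with a PPG channel.
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @return A new `signal_record` with the corrupted PPG channel.
#' @export
inject_artifacts <- function(record, noise, seed = 1) {
  if (!"PPG" %in% names(record$channels)) stopf("record has no PPG channel")
  out <- record
  out$channels$PPG <- with_seed(seed,
    inject_artifacts_values(record$channels$PPG, noise, record$fs))
  out
}

# Core artifact injection on a bare sample vector (uses the current RNG
# stream, so generate_cohort can call it inside its own seeded block).
inject_artifacts_values <- function(x, noise, fs) {
  n <- length(x)
  dur_min <- n / fs / 60
  pa <- diff(range(x))
  if (pa == 0) pa <- 1
  if (noise$baseline_wander_amp > 0) {
    f <- runif(1, 0.1, 0.4)
    phi <- runif(1, 0, 2 * pi)
    x <- x + noise$baseline_wander_amp * pa * sin(2 * pi * f * (seq_len(n) - 1L) / fs + phi)
  }
  if (noise$hf_noise_sd > 0) {
    x <- x + rnorm(n, 0, noise$hf_noise_sd * pa)
  }
  if (noise$amplitude_jump_rate > 0) {
    k <- stats::rpois(1, noise$amplitude_jump_rate * dur_min)
    if (k > 0) {
      at <- sort(sample.int(n, k))
      gains <- runif(k, 0.3, 2)
      for (j in seq_len(k)) {
        lo <- at[j]
        hi <- if (j < k) at[j + 1L] - 1L else n
        x[lo:hi] <- x[lo:hi] * gains[j]
      }
    }
  }
  if (noise$dropout_rate > 0) {
    k <- stats::rpois(1, noise$dropout_rate * dur_min)
    if (k > 0) {
      at <- sample.int(n, k)
      lens <- round(runif(k, 0.5, 2) * fs)
      for (j in seq_len(k)) {
        x[at[j]:min(at[j] + lens[j] - 1L, n)] <- 0
      }
    }
  }
  x
}
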