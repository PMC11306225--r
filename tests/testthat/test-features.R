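test_that("beat detection finds clean synthetic beats and rejects flat lines", {
  fs <- 125
  ppg <- rep(generate_beat(60, 0.25, 1, fs), 10)  # 10 s at 60 bpm
  beats <- detect_beats(ppg, fs)
  expect_true(abs(length(beats$indices) - 10L) <= 1L)
  ibi <- diff(beats$refined) / fs
  expect_true(all(abs(ibi - 1.0) <= 0.02))
  expect_length(detect_beats(rep(0.7, 1250), fs)$indices, 0L)
})

test_that("beat detection survives artifact injection within 50 ms", {
  gen <- generate_cohort(scenario_config(n_patients = 1, records_per_patient = 1,
                                         record_s = 120, seed = 9))
  rec <- gen$cohort[[1L]]
  noisy <- inject_artifacts(rec, noise_config(baseline_wander_amp = 0.1,
                                              hf_noise_sd = 0.05,
                                              dropout_rate = 0.3,
                                              amplitude_jump_rate = 0.3), seed = 5)
  truth_beats <- detect_beats(rec$channels$PPG, rec$fs)
  found <- detect_beats(bandpass(noisy$channels$PPG, rec$fs), rec$fs)
  hit <- vapply(truth_beats$refined, function(p)
    min(abs(found$refined - p)) <= 0.05 * rec$fs, TRUE)
  expect_gte(mean(hit), 0.90)
})

test_that("heart rate is the inverse median inter-beat interval", {
  fs <- 100
  mk_beats <- function(ibis) {
    idx <- cumsum(c(10, round(ibis * fs)))
    pulsecheck:::new_beat_set(idx, fs, "PPG")
  }
  expect_equal(heart_rate(mk_beats(c(0.75, 0.75, 0.75))), 80)
  expect_equal(heart_rate(mk_beats(c(0.5, 1.0, 0.5))), 120)  # median 0.5 s
  expect_true(is.na(heart_rate(pulsecheck:::new_beat_set(5L, fs, "PPG"))))
})

test_that("SDNN is the population SD of NN intervals and scales linearly", {
  fs <- 1000
  mk_beats <- function(ibis) {
    idx <- cumsum(c(10, round(ibis * fs)))
    pulsecheck:::new_beat_set(idx, fs, "PPG")
  }
  expect_equal(sdnn(mk_beats(c(0.8, 0.8, 0.8))), 0)
  # population SD of {0.7, 0.8, 0.9}: sqrt(0.02 / 3) = 0.0816497
  expect_equal(sdnn(mk_beats(c(0.7, 0.8, 0.9))), sqrt(0.02 / 3), tolerance = 1e-9)
  expect_equal(sdnn(mk_beats(2 * c(0.7, 0.8, 0.9))),
               2 * sdnn(mk_beats(c(0.7, 0.8, 0.9))), tolerance = 1e-6)
  expect_true(is.na(sdnn(mk_beats(0.8))))
})

test_that("long windows subdivide SDNN into per-minute sections", {
  fs <- 100
  set.seed(8)
  ibis1 <- rnorm(70, 0.8, 0.01)   # ~56 s
  ibis2 <- rnorm(70, 0.8, 0.05)
  idx <- cumsum(c(10, round(c(ibis1, ibis2) * fs)))
  beats <- pulsecheck:::new_beat_set(idx, fs, "PPG")
  v <- sdnn(beats, subdiv_s = 60)
  # mean of per-minute SDs, not the pooled SD
  pooled <- sd(diff(idx) / fs)
  expect_lt(v, pooled)
})

test_that("the systolic ramp matches a constructed triangle and is homogeneous", {
  fs <- 100
  # two triangular beats: rise 0 -> 1 over 0.2 s, fall back over 0.8 s
  rise <- seq(0, 1, length.out = 21)[-21]
  fall <- seq(1, 0, length.out = 81)[-81]
  x <- c(rise, fall, rise, fall, rise)
  beats <- detect_beats(x, fs)
  v <- systolic_ramp(x, beats, fs)
  expect_equal(v, 5, tolerance = 0.05)         # (1 - 0) / 0.2 s * 1 s duration
  expect_equal(systolic_ramp(2 * x, beats, fs), 2 * v, tolerance = 1e-9)
  # no complete beat -> missing
  expect_true(is.na(systolic_ramp(rise, pulsecheck:::new_beat_set(20L, fs, "PPG"), fs)))
})

test_that("systolic ramps order by configured rise width", {
  fs <- 125
  ramp_of <- function(width) {
    x <- rep(generate_beat(70, 0.2, 1, fs, sys_width_s = width), 8)
    systolic_ramp(x, detect_beats(x, fs), fs)
  }
  v <- c(ramp_of(0.03), ramp_of(0.045), ramp_of(0.06))
  expect_true(all(diff(v) < 0))  # wider rise -> shallower ramp
})

test_that("rPAT is the median preceding-R delay and handles edge cases", {
  fs <- 1000
  ecg <- pulsecheck:::new_beat_set(c(100L, 1100L, 2100L), fs, "ECG")
  ppg <- pulsecheck:::new_beat_set(c(350L, 1350L, 2350L), fs, "PPG")
  expect_equal(rpat(ecg, ppg), 0.25)
  expect_equal(1 / rpat(ecg, ppg), 4.0)
  # R-peaks only after all PPG peaks -> missing
  late_ecg <- pulsecheck:::new_beat_set(3000L, fs, "ECG")
  expect_true(is.na(rpat(late_ecg, ppg)))
})

test_that("feature invariances: offsets and scalings behave as dimensioned", {
  fs <- 125
  set.seed(15)
  x <- rep(generate_beat(70, 0.22, 1, fs), 12)[1:1000] + rnorm(1000, 0, 0.02)
  b0 <- detect_beats(x, fs)
  b_shift <- detect_beats(x + 50, fs)
  b_scale <- detect_beats(5 * x, fs)
  expect_equal(heart_rate(b_shift), heart_rate(b0), tolerance = 1e-6)
  expect_equal(heart_rate(b_scale), heart_rate(b0), tolerance = 1e-6)
  expect_equal(sdnn(b_scale), sdnn(b0), tolerance = 1e-6)
  expect_equal(systolic_ramp(x + 50, b_shift, fs), systolic_ramp(x, b0, fs),
               tolerance = 1e-2)
})

test_that("cohort feature extraction recovers generator HR and rPAT", {
  gen <- clean_cohort()
  ft <- extract_features_cohort(gen$cohort, segmentation_spec(10, 0, "PPG"))
  tr <- gen$truth
  hr_err <- rpat_err <- numeric(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    rows <- tr$patient_id == ft$patient_id[i] & tr$record_id == ft$record_id[i] &
      tr$start_index >= ft$start_index[i] & tr$start_index < ft$start_index[i] + 1250
    hr_err[i] <- abs(ft$HR[i] - mean(tr$hr[rows]))
    rpat_err[i] <- abs(ft$rPAT[i] - tr$pat[rows][1L])
  }
  expect_gte(mean(hr_err <= 1, na.rm = TRUE), 0.95)
  expect_gte(mean(rpat_err <= 0.010, na.rm = TRUE), 0.95)
  # column completeness: failures are flagged as NA, never silent zeros
  expect_true(all(is.finite(ft$HR)))
  expect_true(all(is.finite(ft$Quality)))
  expect_false(any(ft$Quality == 0))
})

test_that("quality score drops under dropouts and zeroes on flat lines", {
  fs <- 125
  clean <- rep(generate_beat(70, 0.2, 1, fs), 12)[1:1000]
  expect_gte(quality_score(clean, fs), 0.9)
  half <- clean
  half[501:1000] <- 0
  expect_lte(quality_score(half, fs), quality_score(clean, fs) - 0.15)
  expect_equal(quality_score(rep(1, 1000), fs), 0)
})

test_that("delta and std feature columns reference the subject baseline", {
  gen <- generate_cohort(scenario_config(n_patients = 2, records_per_patient = 2,
                                         record_s = 120, seed = 25))
  ft <- extract_features_cohort(gen$cohort, segmentation_spec(10, 0, "PPG"))
  baseline <- ft$record_id == "R01"
  out <- delta_and_std_features(ft, baseline, features = c("HR", "dpdt"),
                                period_s = 60)
  # subject means over baseline rows subtract to ~0 on the baseline rows
  base_means <- tapply(out$d.HR[baseline], out$patient_id[baseline], mean,
                       na.rm = TRUE)
  expect_true(all(abs(base_means) < 1e-9))
  # a constant feature has zero fluctuation
  ft2 <- ft
  ft2$HR <- 70
  out2 <- delta_and_std_features(ft2, baseline, features = "HR", period_s = 60)
  expect_true(all(out2$std.HR[is.finite(out2$std.HR)] == 0))
  # identical baseline gives all-zero deltas
  expect_true(all(abs(out2$d.HR) < 1e-9))
})
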