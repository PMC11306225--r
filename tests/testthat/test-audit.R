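# Shared audit fixture: a multi-record cohort segmented into the classic
# 10 s / 5 s overlapping windows.
audit_windows <- function() {
  memo_fixture("audit_ws", {
    gen <- generate_cohort(scenario_config(
      n_patients = 10, records_per_patient = 2, record_s = 120,
      conditioning = "ill", latent_sd = 10,
      noise = noise_config(hf_noise_sd = 0.03), seed = 31))
    bind_windows(lapply(gen$cohort, function(r)
      derive_labels(r, segment(r, segmentation_spec(10, 5, "PPG")), "SBP")))
  })
}

test_that("split modes partition at the declared unit and reproduce by seed", {
  ws <- audit_windows()
  sp <- make_split(ws, split_spec("no_overlap", 0.2, seed = 1))
  expect_equal(length(unique(sp$test$info$patient_id)), 2L)
  expect_length(intersect(unique(sp$train$info$patient_id),
                          unique(sp$test$info$patient_id)), 0L)
  # window objects are never shared in any mode
  for (m in c("no_overlap", "domain_overlap", "data_overlap")) {
    s <- make_split(ws, split_spec(m, 0.2, seed = 2))
    expect_equal(n_windows(s$train) + n_windows(s$test), n_windows(ws))
    key <- function(w) paste(w$info$patient_id, w$info$record_id, w$info$start_index)
    expect_length(intersect(key(s$train), key(s$test)), 0L)
  }
  s1 <- make_split(ws, split_spec("data_overlap", 0.2, seed = 5))
  s2 <- make_split(ws, split_spec("data_overlap", 0.2, seed = 5))
  expect_identical(s1$test$info, s2$test$info)
  # too few patients for a patient-level split is an error
  one <- ws[ws$info$patient_id == "P01"]
  expect_error(make_split(one, split_spec("no_overlap")), "2 patients")
})

test_that("leakage reports match the split taxonomy and a brute-force count", {
  ws <- audit_windows()
  no <- make_split(ws, split_spec("no_overlap", 0.2, seed = 3))
  lk_no <- detect_leakage(no$train, no$test)
  expect_equal(lk_no$shared_patients, 0L)
  expect_equal(lk_no$shared_records, 0L)
  expect_equal(lk_no$overlapping_sample_pairs, 0L)

  dom <- make_split(ws, split_spec("domain_overlap", 0.2, seed = 3))
  lk_dom <- detect_leakage(dom$train, dom$test)
  expect_gt(lk_dom$shared_patients, 0L)
  expect_equal(lk_dom$shared_records, 0L)
  expect_equal(lk_dom$overlapping_sample_pairs, 0L)

  dat <- make_split(ws, split_spec("data_overlap", 0.2, seed = 3))
  lk_dat <- detect_leakage(dat$train, dat$test)
  expect_gt(lk_dat$overlapping_sample_pairs, 0L)
  expect_equal(lk_dat$overlapping_sample_pairs,
               oracle_overlap_pairs(dat$train, dat$test))
})

test_that("error statistics and device grades follow their definitions", {
  s <- error_stats(c(125, 115), c(120, 120))  # errors +5, -5
  expect_equal(s$bias, 0)
  expect_equal(s$sd, 5)
  expect_equal(s$mae, 5)
  expect_error(error_stats(numeric(0), numeric(0)), "non-empty")

  expect_equal(grade(errors = c(-4, 3, 2, -1))$bhs_grade, "A")
  expect_true(grade(error_stats(c(4.9, 4.9), c(0, 0)), c(4.9, 4.9))$aami_pass)
  st <- structure(list(bias = 5.1, sd = 7), class = "error_stats")
  expect_false(grade(st, rep(2, 10))$aami_pass)
  st2 <- structure(list(bias = 4.9, sd = 8.0), class = "error_stats")
  expect_true(grade(st2, rep(2, 10))$aami_pass)
  # grade bands: 55/80/92% cumulative fractions -> B
  set.seed(1)
  e <- c(rep(4, 55), rep(9, 25), rep(14, 12), rep(20, 8))
  expect_equal(grade(errors = e)$bhs_grade, "B")
})

test_that("calibration strategies behave exactly on constructed records", {
  # constant true SBP: naive calibration is perfect
  vals <- matrix(rnorm(6 * 50), 6)
  ws <- raw_window_set(vals, data.frame(SBP = rep(120, 6)))
  ws$info$start_day <- (0:5) / 86400
  cal <- calibrate_and_evaluate(ws, NULL, calibration_spec("naive"), "SBP")
  expect_equal(cal$stats$bias, 0)
  expect_equal(cal$stats$sd, 0)
  expect_equal(cal$stats$n, 3L)  # 3 calibration windows excluded

  # predictor = truth + 7: offset calibration removes the bias exactly
  truth <- c(118, 121, 119, 124, 122, 120)
  ws2 <- raw_window_set(vals, data.frame(SBP = truth))
  ws2$info$start_day <- (0:5) / 86400
  cal2 <- calibrate_and_evaluate(ws2, truth + 7, calibration_spec("offset"), "SBP")
  expect_equal(cal2$stats$bias, 0)
  expect_equal(cal2$stats$sd, 0)
  # passing predictions through unchanged reports the raw error
  cal3 <- calibrate_and_evaluate(ws2, truth + 7, calibration_spec("none"), "SBP")
  expect_equal(cal3$stats$bias, 7)
  # a record too short for naive calibration is skipped, not an error
  short <- raw_window_set(vals[1:3, ], data.frame(SBP = truth[1:3]))
  short$info$start_day <- (0:2) / 86400
  cal4 <- calibrate_and_evaluate(short, NULL, calibration_spec("naive"), "SBP")
  expect_equal(cal4$n_skipped_units, 1L)
})

test_that("offset calibration decays over days under per-patient drift", {
  gen <- generate_cohort(scenario_config(
    n_patients = 6, records_per_patient = 11, record_s = 60,
    record_interval_days = 1, drift_per_day = 2, conditioning = "well",
    seed = 17))
  spec10 <- segmentation_spec(10, 0, "PPG")
  ws <- bind_windows(lapply(gen$cohort, function(r)
    derive_labels(r, segment(r, spec10), "SBP")))
  ft <- extract_features_cohort(gen$cohort, spec10)
  pred <- predictor_ridge(ft, ws$labels$SBP)(ft)
  cal <- calibrate_and_evaluate(ws, pred,
                                calibration_spec("offset", scope = "patient"),
                                "SBP", bin_days = 1)
  expect_gte(nrow(cal$decay), 8L)
  rho <- cor(cal$decay$elapsed_days, cal$decay$sd, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("naive calibration beats the uncalibrated plumbing predictor on short records", {
  gen <- generate_cohort(scenario_config(
    n_patients = 6, records_per_patient = 2, record_s = 120, seed = 23))
  spec10 <- segmentation_spec(10, 0, "PPG")
  ws <- bind_windows(lapply(gen$cohort, function(r)
    derive_labels(r, segment(r, spec10), "SBP")))
  ft <- extract_features_cohort(gen$cohort, spec10)
  pred <- predictor_ridge(ft, ws$labels$SBP)(ft)
  naive <- calibrate_and_evaluate(ws, NULL, calibration_spec("naive"), "SBP")
  none <- calibrate_and_evaluate(ws, pred, calibration_spec("none"), "SBP")
  expect_lt(naive$stats$sd, none$stats$sd)
})

test_that("memorizing predictors rank split modes by leakage severity", {
  sds <- sapply(1:3, function(seed) {
    gen <- generate_cohort(scenario_config(
      n_patients = 10, records_per_patient = 2, record_s = 120,
      conditioning = "ill", latent_sd = 10,
      noise = noise_config(hf_noise_sd = 0.03), seed = seed))
    ws <- bind_windows(lapply(gen$cohort, function(r)
      derive_labels(r, segment(r, segmentation_spec(10, 5, "PPG")), "SBP")))
    vapply(c("no_overlap", "domain_overlap", "data_overlap"), function(m) {
      sp <- make_split(ws, split_spec(m, 0.2, seed = seed))
      ok <- is.finite(sp$test$labels$SBP)
      error_stats(predictor_knn(sp$train, "SBP")(sp$test)[ok],
                  sp$test$labels$SBP[ok])$sd
    }, 0.0)
  })
  m <- rowMeans(sds)
  expect_gte(m["no_overlap"], m["domain_overlap"] - 1)
  expect_gte(m["domain_overlap"], m["data_overlap"] - 1)
  expect_gt(m["no_overlap"], m["data_overlap"])
})
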