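# Train/test split taxonomy and leakage detection, calibration strategies
# with time-decay evaluation, and error metrics with AAMI/BHS grading.

#' Train/test split settings
#'
#' @param mode `"no_overlap"` (partition at the patient level),
#'   `"domain_overlap"` (partition at the record level: records of the same
#'   patient may straddle the split) or `"data_overlap"` (partition at the
#'   window level; segment with overlapping windows *before* splitting to
#'   reproduce the classic leakage pattern).
#' @param test_fraction Fraction of units assigned to the test side.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A `split_spec`.
#' @export
split_spec <- function(mode = c("no_overlap", "domain_overlap", "data_overlap"),
                       test_fraction = 0.2, seed = 0) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  structure(list(mode = mode, test_fraction = test_fraction, seed = seed),
            class = "split_spec")
}

#' Split windows into train and test sets
#'
#' The three modes differ only in the unit that is randomized: patients,
#' records, or individual windows. Window objects are never shared between
#' the two sides in any mode; leakage is about shared *content*, which
#' [detect_leakage()] measures.
#'
#' @param ws A `window_set` with provenance.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` window sets.
#' @export
make_split <- function(ws, spec) {
  with_seed(spec$seed, {
    test_rows <- switch(spec$mode,
      no_overlap = {
        pats <- unique(ws$info$patient_id)
        if (length(pats) < 2L) stopf("no_overlap split needs at least 2 patients")
        n_test <- max(1L, round(spec$test_fraction * length(pats)))
        test_p <- sample(pats, n_test)
        which(ws$info$patient_id %in% test_p)
      },
      domain_overlap = {
        recs <- unique(paste(ws$info$patient_id, ws$info$record_id, sep = ":"))
        if (length(recs) < 2L) stopf("domain_overlap split needs at least 2 records")
        n_test <- max(1L, round(spec$test_fraction * length(recs)))
        test_r <- sample(recs, n_test)
        which(paste(ws$info$patient_id, ws$info$record_id, sep = ":") %in% test_r)
      },
      data_overlap = {
        n <- n_windows(ws)
        sample.int(n, max(1L, round(spec$test_fraction * n)))
      }
    )
    list(train = ws[setdiff(seq_len(n_windows(ws)), test_rows)],
         test = ws[test_rows])
  })
}

#' Measure train/test contamination
#'
#' Counts patients and records present on both sides, and the number of
#' train/test window pairs that share at least one raw sample (interval
#' intersection of `[start, start + len)` within the same record).
#'
#' @param train,test `window_set`s from [make_split()].
#' @return A `leakage_report` with `shared_patients`, `shared_records`,
#'   `overlapping_sample_pairs`.
#' @export
detect_leakage <- function(train, test) {
  shared_patients <- length(intersect(unique(train$info$patient_id),
                                      unique(test$info$patient_id)))
  rid_tr <- unique(paste(train$info$patient_id, train$info$record_id, sep = ":"))
  rid_te <- unique(paste(test$info$patient_id, test$info$record_id, sep = ":"))
  shared_records <- length(intersect(rid_tr, rid_te))
  len <- ncol(train$values)
  pairs <- 0L
  key_tr <- paste(train$info$patient_id, train$info$record_id, sep = ":")
  key_te <- paste(test$info$patient_id, test$info$record_id, sep = ":")
  for (rec in intersect(rid_tr, rid_te)) {
    a <- train$info$start_index[key_tr == rec]
    b <- test$info$start_index[key_te == rec]
    for (s in a) pairs <- pairs + sum(b < s + len & s < b + len)
  }
  structure(list(shared_patients = shared_patients,
                 shared_records = shared_records,
                 overlapping_sample_pairs = pairs),
            class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf("<leakage_report> shared patients %d, shared records %d, sample-overlapping pairs %d\n",
              x$shared_patients, x$shared_records, x$overlapping_sample_pairs))
  invisible(x)
}

#' Calibration settings
#'
#' Naive calibration predicts a constant per unit: the mean of the ground
#' truth labels of the unit's first three windows. Offset calibration adds
#' a constant to every prediction: the truth-minus-prediction difference on
#' the unit's first window. Calibration windows are excluded from
#' evaluation.
#'
#' @param method `"naive"`, `"offset"` or `"none"`.
#' @param scope Calibration unit: `"record"` (the classic per-record
#'   definition) or `"patient"` (calibrate once on the patient's first
#'   record, appropriate for day-scale decay analyses).
#' @param n_naive Windows averaged for naive calibration (default 3).
#' @return A `calibration_spec`.
#' @export
calibration_spec <- function(method = c("naive", "offset", "none"),
                             scope = c("record", "patient"), n_naive = 3L) {
  structure(list(method = match.arg(method), scope = match.arg(scope),
                 n_naive = as.integer(n_naive)),
            class = "calibration_spec")
}

#' Apply a calibration strategy and evaluate errors over time
#'
#' Windows are processed per calibration unit in time order. Naive
#' calibration ignores the predictor entirely; offset calibration shifts
#' every predictor output by the constant fitted on the first window; none
#' passes predictions through. Errors over all post-calibration windows
#' give the overall [error_stats()]; a decay curve bins the errors by
#' elapsed time since the calibration window.
#'
#' @param ws A labeled `window_set` whose `info` carries `start_day`.
#' @param predictions Numeric vector of predictor outputs aligned with the
#'   windows (may be `NULL` for naive calibration).
#' @param spec A [calibration_spec()].
#' @param target Label column (default `"SBP"`).
#' @param bin_days Decay-curve bin width in days (default 1).
#' @return List with `stats` (an `error_stats`), `decay` (data frame:
#'   `elapsed_days` bin midpoint, `bias`, `sd`, `n`) and `n_skipped_units`.
#' @export
calibrate_and_evaluate <- function(ws, predictions = NULL,
                                   spec = calibration_spec("naive"),
                                   target = "SBP", bin_days = 1) {
  truth <- ws$labels[[target]]
  if (is.null(truth)) stopf("windows carry no '%s' labels", target)
  if (spec$method != "naive") {
    if (is.null(predictions) || length(predictions) != n_windows(ws))
      stopf("method '%s' needs one prediction per window", spec$method)
  }
  unit <- if (spec$scope == "record") {
    paste(ws$info$patient_id, ws$info$record_id, sep = ":")
  } else ws$info$patient_id
  time_days <- ws$info$start_day
  err <- rep(NA_real_, n_windows(ws))
  elapsed <- rep(NA_real_, n_windows(ws))
  skipped <- 0L
  for (u in unique(unit)) {
    rows <- which(unit == u & is.finite(truth))
    rows <- rows[order(time_days[rows])]
    n_cal <- if (spec$method == "naive") spec$n_naive
             else if (spec$method == "offset") 1L else 0L
    if (length(rows) < n_cal + 1L) { skipped <- skipped + 1L; next }
    cal_rows <- head(rows, n_cal)
    eval_rows <- rows[(n_cal + 1L):length(rows)]
    pred <- switch(spec$method,
      naive = rep(mean(truth[cal_rows]), length(eval_rows)),
      offset = predictions[eval_rows] +
        (truth[cal_rows[1L]] - predictions[cal_rows[1L]]),
      none = predictions[eval_rows]
    )
    err[eval_rows] <- pred - truth[eval_rows]
    t0 <- if (n_cal > 0L) max(time_days[cal_rows]) else min(time_days[rows])
    elapsed[eval_rows] <- time_days[eval_rows] - t0
  }
  ok <- is.finite(err)
  if (!any(ok)) {
    return(list(stats = NULL, decay = NULL, n_skipped_units = skipped))
  }
  stats <- error_stats(err[ok] + 0, rep(0, sum(ok)))  # err already pred - truth
  bins <- floor(elapsed[ok] / bin_days)
  decay <- do.call(rbind, lapply(sort(unique(bins)), function(bk) {
    e <- err[ok][bins == bk]
    data.frame(elapsed_days = (bk + 0.5) * bin_days,
               bias = mean(e), sd = pop_sd(e), n = length(e))
  }))
  list(stats = stats, decay = decay, n_skipped_units = skipped)
}

#' Prediction error statistics
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @return An `error_stats` with `bias` (mean error), `sd` (population SD
#'   of the error), `mae` and `n`.
#' @export
error_stats <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(predictions) == 0L)
    stopf("predictions and truths must be equal-length and non-empty")
  e <- predictions - truths
  structure(list(bias = mean(e), sd = pop_sd(e), mae = mean(abs(e)),
                 n = length(e)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> bias %.2f, SD %.2f, MAE %.2f (n = %d)\n",
              x$bias, x$sd, x$mae, x$n))
  invisible(x)
}

#' AAMI pass/fail and BHS grade
#'
#' AAMI: |bias| <= 5 mmHg and error SD <= 8 mmHg (inclusive bounds). BHS
#' grades from the cumulative fractions of absolute errors within 5, 10
#' and 15 mmHg: A requires 60/85/95%, B 50/75/90%, C 40/65/85%, else D.
#'
#' @param stats An `error_stats` (or `NULL` to compute from `errors`).
#' @param errors Vector of signed errors (pred - truth), mmHg.
#' @return A `standards_grade` with `aami_pass`, `bhs_grade` and the
#'   cumulative fractions.
#' @export
grade <- function(stats = NULL, errors) {
  if (is.null(stats)) stats <- error_stats(errors, rep(0, length(errors)))
  p5 <- mean(abs(errors) <= 5)
  p10 <- mean(abs(errors) <= 10)
  p15 <- mean(abs(errors) <= 15)
  bhs <- if (p5 >= 0.60 && p10 >= 0.85 && p15 >= 0.95) "A"
  else if (p5 >= 0.50 && p10 >= 0.75 && p15 >= 0.90) "B"
  else if (p5 >= 0.40 && p10 >= 0.65 && p15 >= 0.85) "C"
  else "D"
  structure(list(aami_pass = abs(stats$bias) <= 5 && stats$sd <= 8,
                 bhs_grade = bhs, p5 = p5, p10 = p10, p15 = p15),
            class = "standards_grade")
}

#' @export
print.standards_grade <- function(x, ...) {
  cat(sprintf("<standards_grade> AAMI %s; BHS grade %s (<=5/10/15 mmHg: %.0f/%.0f/%.0f%%)\n",
              if (x$aami_pass) "pass" else "fail", x$bhs_grade,
              100 * x$p5, 100 * x$p10, 100 * x$p15))
  invisible(x)
}

#' Ridge-regression plumbing predictor on handcrafted features
#'
#' A deliberately simple predictor used to exercise the audit machinery;
#' it makes no claim to blood-pressure accuracy. Missing feature values are
#' imputed with training-column medians.
#'
#' @param features Training feature data frame (e.g. from
#'   [extract_features_cohort()]).
#' @param y Training target vector.
#' @param cols Feature columns to use.
#' @param lambda Ridge penalty (default 0.01).
#' @return A function mapping a feature data frame to predictions.
#' @export
predictor_ridge <- function(features, y,
                            cols = c("HR", "SDNN", "Quality", "dpdt"),
                            lambda = 0.01) {
  cols <- intersect(cols, names(features))
  X <- as.matrix(features[cols])
  med <- apply(X, 2L, median, na.rm = TRUE)
  for (j in seq_along(cols)) X[!is.finite(X[, j]), j] <- med[j]
  ok <- is.finite(y)
  fit <- glmnet::glmnet(X[ok, , drop = FALSE], y[ok], alpha = 0,
                        lambda = c(10, 1, 0.1, lambda))
  function(newdata) {
    Xn <- as.matrix(newdata[cols])
    for (j in seq_along(cols)) Xn[!is.finite(Xn[, j]), j] <- med[j]
    as.numeric(stats::predict(fit, Xn, s = lambda))
  }
}

#' Nearest-neighbour window predictor
#'
#' Predicts a test window's label as the label of its nearest training
#' window, using the minimum Euclidean distance over all circular shifts
#' (computed batch-wise via the FFT cross-correlation identity) on
#' per-record min-max normalized values. This is the minimal memorizing
#' predictor: unlike the ridge model it can exploit shared raw samples or
#' shared patient identity between train and test, which is exactly what
#' the split-leakage ranking audit measures.
#'
#' @param train A labeled `window_set` (training side).
#' @param target Label column.
#' @return A function mapping a `window_set` to predictions.
#' @export
predictor_knn <- function(train, target = "SBP") {
  y <- train$labels[[target]]
  ok <- is.finite(y)
  A <- t(normalize_windows(train[ok])$values)
  y <- y[ok]
  FA <- stats::mvfft(A)
  sqA <- colSums(A^2)
  function(ws) {
    B <- t(normalize_windows(ws)$values)
    FB <- stats::mvfft(B)
    vapply(seq_len(ncol(B)), function(i) {
      cc <- Re(stats::mvfft(FA * Conj(FB[, i]), inverse = TRUE)) / nrow(A)
      d2 <- sum(B[, i]^2) + sqA - 2 * apply(cc, 2L, max)
      y[which.min(d2)]
    }, 0.0)
  }
}
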