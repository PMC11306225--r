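# Shared fixtures (memoized: several test files reuse the same synthetic
# cohorts) and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A clean 3-patient cohort used for feature-recovery and label checks.
clean_cohort <- function() {
  memo_fixture("clean3", generate_cohort(
    scenario_config(n_patients = 3, records_per_patient = 1, record_s = 360,
                    seed = 5)))
}

# Small intra-patient cohorts with the conditioning dial set.
dial_cohort <- function(latent_sd, seed = 21) {
  memo_fixture(sprintf("dial_%g_%d", latent_sd, seed), generate_cohort(
    scenario_config(n_patients = 6, records_per_patient = 2, record_s = 240,
                    conditioning = if (latent_sd > 0) "ill" else "well",
                    latent_sd = latent_sd, seed = seed)))
}

labeled_2s_windows <- function(gen) {
  attach_labels(segment_cohort(gen$cohort, segmentation_spec(2, 0, "PPG")),
                gen$truth)
}

# Minimal independent WFDB format-16 writer (bytes per the format
# definition); the package deliberately has no WFDB write support, so this
# is the round-trip oracle for the reader.
write_wfdb16 <- function(dir, name, digital, fs, gains, descs, baselines = NULL) {
  n_sig <- length(digital)
  n <- length(digital[[1L]])
  baselines <- baselines %||% rep(0L, n_sig)
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  inter <- as.integer(do.call(rbind, digital))
  writeBin(inter, con, size = 2L, endian = "little")
  close(con)
  lines <- c(sprintf("%s %d %g %d", name, n_sig, fs, n),
             vapply(seq_len(n_sig), function(j)
               sprintf("%s.dat 16 %g(%d)/NU 16 0 0 0 0 %s",
                       name, gains[j], baselines[j], descs[j]), ""))
  writeLines(lines, file.path(dir, paste0(name, ".hea")))
  file.path(dir, paste0(name, ".hea"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive R-level multi-valued-mapping oracle built on the exported
# single-pair operations align()/pair_distance(); independent of the C++
# search path.
oracle_find_matches <- function(ws, target, cfg) {
  sub <- ws[is.finite(ws$labels[[target]])]
  sub <- normalize_windows(sub)
  y <- sub$labels[[target]]
  pid <- sub$info$patient_id
  n <- n_windows(sub)
  matched <- rep(FALSE, n)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- pid[i] == pid[j]
      if ((cfg$scope == "intra_patient") != same) next
      if (abs(y[i] - y[j]) < cfg$output_threshold) next
      d <- pair_distance(sub$values[i, ], sub$values[j, ], sub$fs, cfg)
      if (d <= cfg$input_threshold) {
        matched[i] <- matched[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  list(matched = matched, n_matched = sum(matched),
       pairs = do.call(rbind, pairs))
}

# Brute-force count of train/test window pairs sharing raw samples.
oracle_overlap_pairs <- function(train, test) {
  len <- ncol(train$values)
  cnt <- 0L
  for (a in seq_len(n_windows(train))) {
    for (b in seq_len(n_windows(test))) {
      if (train$info$patient_id[a] != test$info$patient_id[b]) next
      if (train$info$record_id[a] != test$info$record_id[b]) next
      sa <- train$info$start_index[a]; sb <- test$info$start_index[b]
      if (sb < sa + len && sa < sb + len) cnt <- cnt + 1L
    }
  }
  cnt
}

# Window set built directly from a value matrix (for planted designs).
raw_window_set <- function(values, labels, patient_id = "P1", fs = 125) {
  info <- data.frame(patient_id = patient_id, record_id = "R1",
                     start_index = seq_len(nrow(values)), start_day = 0,
                     stringsAsFactors = FALSE)
  pulsecheck:::new_window_set(values, info, labels, fs, ncol(values) / fs, "PPG")
}

# Planted multi-valued design: n windows total, a fraction p of which have
# a near-identical partner whose label differs by `delta`.
planted_design <- function(n = 1000, p = 0.2, delta = 15, seed = 11, fs = 125,
                           L = 250) {
  set.seed(seed)
  n_dup <- round(p * n / 2)
  n_base <- n - n_dup
  mk <- function(m) t(sapply(seq_len(m), function(i) {
    ph <- runif(1, 0, 2 * pi); f <- runif(1, 0.8, 1.6)
    sin(2 * pi * f * (0:(L - 1)) / fs + ph) +
      0.3 * sin(4 * pi * f * (0:(L - 1)) / fs) + rnorm(L, 0, 0.3)
  }))
  base <- mk(n_base)
  vals <- rbind(base, base[seq_len(n_dup), , drop = FALSE])
  y <- runif(n_base, 100, 140)
  labels <- data.frame(SBP = c(y, y[seq_len(n_dup)] + delta))
  list(ws = raw_window_set(vals, labels, fs = fs), planted_fraction = 2 * n_dup / n)
}
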