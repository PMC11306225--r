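test_that("cross-correlation alignment recovers circular shifts exactly", {
  set.seed(1)
  x <- sin(2 * pi * (0:249) / 100) + rnorm(250, 0, 0.01)
  y <- pulsecheck:::circ_shift(x, 10)  # y[t] = x[t - 10]
  al <- align(x, y, fs = 125)
  expect_equal(al$lag, -10L)
  expect_equal(sqrt(sum((x - al$aligned)^2)), 0, tolerance = 1e-9)

  # identity aligns at lag 0; zero-variance input is defined, not an error
  expect_equal(align(x, x, 125)$lag, 0L)
  flat <- align(rep(1, 250), rep(2, 250), 125)
  expect_equal(flat$lag, 0L)
  expect_equal(flat$corr, 0)

  # brute-force exactness over random shifts of periodic windows
  set.seed(77)
  ok <- vapply(1:100, function(i) {
    f <- runif(1, 0.8, 1.5)
    base <- sin(2 * pi * f * (0:249) / 125) + 0.4 * sin(4 * pi * f * (0:249) / 125 + 1)
    lag <- sample(-40:40, 1)
    al <- align(base, pulsecheck:::circ_shift(base, lag), 125)
    isTRUE(all.equal(sum((base - al$aligned)^2), 0, tolerance = 1e-12))
  }, TRUE)
  expect_equal(mean(ok), 1)
})

test_that("pair distance is a symmetric aligned L2 norm with boundary inclusion", {
  set.seed(2)
  x <- rnorm(250)
  expect_equal(pair_distance(x, x, 125), 0)
  # a per-sample mean-squared difference of 4e-3 is exactly distance 1.0
  # over 250 samples, and the boundary counts as a match (inclusive)
  y <- x + sqrt(4e-3)
  d <- pair_distance(x, y, 125)
  expect_equal(d, 1.0, tolerance = 1e-12)
  # the threshold boundary itself counts as a match (inclusive comparison);
  # windows differing in exactly one sample by 1.0 have distance exactly 1.0
  u <- rep(0, 250)
  v <- c(1, rep(0, 249))
  expect_equal(pair_distance(u, v, 125), 1.0)
  ws_b <- raw_window_set(rbind(u, v), data.frame(SBP = c(110, 130)))
  rb <- find_matches(ws_b, "SBP", mvmap_config(1.0, 8, "intra_patient"),
                     normalize = FALSE)
  expect_equal(rb$n_matched, 2L)
  expect_error(pair_distance(x, rnorm(100)), "equal length")
  for (i in 1:20) {
    a <- rnorm(250); b <- rnorm(250)
    expect_equal(pair_distance(a, b, 125), pair_distance(b, a, 125),
                 tolerance = 1e-9)
  }
})

test_that("trivial match configurations count windows, not pairs", {
  w <- sin(2 * pi * (0:249) / 90)
  # 3 copies with labels within the output threshold: no matches
  ws <- raw_window_set(rbind(w, w, w), data.frame(SBP = c(120, 120, 121)))
  r <- find_matches(ws, "SBP", mvmap_config(1.0, 8, "intra_patient"),
                    normalize = FALSE)
  expect_equal(r$n_matched, 0L)
  expect_equal(nrow(r$pairs), 0L)

  # 2 identical windows, labels 20 mmHg apart: both matched, 100%
  ws2 <- raw_window_set(rbind(w, w), data.frame(SBP = c(110, 130)))
  r2 <- find_matches(ws2, "SBP", mvmap_config(1.0, 8, "intra_patient"),
                     normalize = FALSE)
  expect_equal(r2$n_matched, 2L)
  expect_equal(r2$match_fraction, 100)
  expect_equal(nrow(r2$pairs), 1L)
})

test_that("scope partitions intra- and inter-patient pairs disjointly", {
  set.seed(31)
  vals <- matrix(rnorm(40 * 250, sd = 0.05), 40) +
    matrix(rep(sin(2 * pi * (0:249) / 80), each = 40), 40)
  labels <- data.frame(SBP = runif(40, 90, 150))
  ws <- raw_window_set(vals, labels,
                       patient_id = rep(c("A", "B"), each = 20))
  intra <- find_matches(ws, "SBP", mvmap_config(3, 8, "intra_patient"))
  inter <- find_matches(ws, "SBP", mvmap_config(3, 8, "inter_patient"))
  pid <- ws$info$patient_id
  if (nrow(intra$pairs)) {
    expect_true(all(pid[intra$pairs$i] == pid[intra$pairs$j]))
  }
  if (nrow(inter$pairs)) {
    expect_true(all(pid[inter$pairs$i] != pid[inter$pairs$j]))
  }
  # together the two scopes examine every qualifying pair exactly once
  loose_in <- find_matches(ws, "SBP", mvmap_config(1e6, 1e-9, "intra_patient"))
  loose_out <- find_matches(ws, "SBP", mvmap_config(1e6, 1e-9, "inter_patient"))
  expect_equal(nrow(loose_in$pairs) + nrow(loose_out$pairs), choose(40, 2))
})

test_that("match fraction is monotone in both thresholds", {
  d <- planted_design(n = 300, p = 0.2, seed = 41)
  fr_in <- vapply(c(0.5, 1.0, 2.0, 5.0), function(th)
    find_matches(d$ws, "SBP", mvmap_config(th, 8, "intra_patient"),
                 normalize = FALSE)$match_fraction, 0.0)
  expect_true(all(diff(fr_in) >= 0))
  fr_out <- vapply(c(2, 8, 14, 16), function(th)
    find_matches(d$ws, "SBP", mvmap_config(1.0, th, "intra_patient"),
                 normalize = FALSE)$match_fraction, 0.0)
  expect_true(all(diff(fr_out) <= 0))
})

test_that("the optimized search equals the exhaustive R oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60
    vals <- matrix(rnorm(n * 250, sd = 0.2), n) +
      outer(rep(1, n), sin(2 * pi * (0:249) / 85)) * runif(n, 0.5, 1.5)
    ws <- raw_window_set(vals, data.frame(SBP = runif(n, 100, 140)),
                         patient_id = sample(c("A", "B"), n, replace = TRUE))
    cfg <- mvmap_config(4.0, 8, "intra_patient")
    fast <- find_matches(ws, "SBP", cfg)
    slow <- oracle_find_matches(ws, "SBP", cfg)
    expect_identical(as.logical(fast$matched), slow$matched)
    expect_equal(fast$n_matched, slow$n_matched)
    if (!is.null(slow$pairs)) {
      expect_equal(fast$pairs[c("i", "j")],
                   as.data.frame(slow$pairs) |> setNames(c("i", "j")),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the pre-screen never changes the result set", {
  for (seed in 1:3) {
    d <- planted_design(n = 200, p = 0.15, seed = 100 + seed)
    cfg <- mvmap_config(1.0, 8, "intra_patient")
    on_ <- find_matches(d$ws, "SBP", cfg, prescreen = TRUE)
    off <- find_matches(d$ws, "SBP", cfg, prescreen = FALSE)
    expect_identical(on_$matched, off$matched)
    expect_identical(on_$pairs, off$pairs)
  }
})

test_that("unlabeled windows are excluded from the search and counted", {
  w <- sin(2 * pi * (0:249) / 90)
  ws <- raw_window_set(rbind(w, w, w), data.frame(SBP = c(110, NA, 130)))
  r <- find_matches(ws, "SBP", mvmap_config(1.0, 8, "intra_patient"),
                    normalize = FALSE)
  expect_equal(r$n_unlabeled, 1L)
  expect_equal(r$n_windows, 2L)
  expect_equal(r$n_matched, 2L)
})
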