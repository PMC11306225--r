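# k-nearest-neighbour mutual information, target entropy, and the
# Info-Fraction ratio MI / H(target): the fraction of the target's
# uncertainty that the features explain, with the target entropy as the
# ceiling on achievable mutual information.

#' Mutual-information estimator settings
#'
#' @param k Neighbour count for the kNN estimators (default 3).
#' @param estimator `"mixed_discrete"` (continuous features vs a target
#'   quantized at sensor resolution; the default, and the mode used for
#'   Info-Fraction ratios) or `"ksg_continuous"` (the classic
#'   Kraskov-type estimator for two continuous variables).
#' @param target_resolution Quantization step for the discrete target
#'   entropy: 1 mmHg for SBP, 1 bpm for HR, 0.01 s for RWAT are sensible
#'   choices.
#' @param standardize z-score feature columns before distance computation
#'   (default `TRUE`).
#' @param seed Seed for the infinitesimal tie-breaking jitter.
#' @return An `mi_config`.
#' @export
mi_config <- function(k = 3, estimator = c("mixed_discrete", "ksg_continuous"),
                      target_resolution = 1, standardize = TRUE, seed = 0) {
  estimator <- match.arg(estimator)
  if (k < 1) stopf("k must be >= 1")
  if (target_resolution <= 0) stopf("target_resolution must be > 0")
  structure(list(k = as.integer(k), estimator = estimator,
                 target_resolution = target_resolution,
                 standardize = standardize, seed = seed),
            class = "mi_config")
}

# Standardize columns and add seeded jitter of 1e-10 column SD so the
# continuity assumption of the kNN estimators holds even with repeated
# values.
prep_features <- function(X, cfg) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (cfg$standardize) {
    X <- apply(X, 2L, function(col) {
      s <- sd(col)
      if (is.finite(s) && s > 0) (col - mean(col)) / s else col - mean(col)
    })
    X <- matrix(X, nrow = NROW(X))
  }
  with_seed(cfg$seed, {
    jit <- matrix(rnorm(length(X)), nrow(X), ncol(X))
    sds <- apply(X, 2L, pop_sd)
    sds[sds == 0] <- 1
    X + sweep(jit, 2L, 1e-10 * sds, "*")
  })
}

drop_missing_rows <- function(X, y) {
  X <- as.matrix(X)
  ok <- is.finite(y) & apply(X, 1L, function(r) all(is.finite(r)))
  if (!all(ok))
    message(sprintf("dropping %d rows with missing values", sum(!ok)))
  list(X = X[ok, , drop = FALSE], y = y[ok])
}

#' kNN mutual information between features and a continuous target
#'
#' Kraskov-type k-nearest-neighbour estimate (first variant) in nats, on
#' standardized columns with seeded infinitesimal jitter; clamped at 0.
#' With `estimator = "mixed_discrete"` the target is quantized at
#' `target_resolution` and the mixed continuous-discrete neighbour
#' estimator is used instead.
#'
#' @param X Feature matrix (rows = observations) or vector.
#' @param y Target vector.
#' @param cfg An [mi_config()].
#' @return MI in nats (>= 0). A constant target returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
knn_mi <- function(X, y, cfg = mi_config(estimator = "ksg_continuous")) {
  d <- drop_missing_rows(X, y)
  if (length(d$y) < 50) stopf("need at least 50 complete rows (got %d)", length(d$y))
  if (pop_sd(d$y) == 0)
    return(structure(0, degenerate = TRUE))
  Xp <- prep_features(d$X, cfg)
  mi <- if (cfg$estimator == "ksg_continuous") {
    yp <- as.numeric(prep_features(matrix(d$y, ncol = 1L), cfg))
    cpp_ksg_mi(Xp, yp, cfg$k)
  } else {
    cls <- as.integer(factor(floor(d$y / cfg$target_resolution)))
    cpp_mixed_mi(Xp, cls, cfg$k)
  }
  max(0, mi)
}

#' Plug-in entropy of a quantized target
#'
#' Discrete Shannon entropy (nats) of the target binned at
#' `target_resolution`.
#'
#' @param y Target vector.
#' @param cfg An [mi_config()].
#' @return Entropy in nats (0 for a constant target).
#' @export
target_entropy <- function(y, cfg = mi_config()) {
  y <- y[is.finite(y)]
  if (length(y) < 50) stopf("need at least 50 values")
  p <- table(floor(y / cfg$target_resolution)) / length(y)
  -sum(p * log(p))
}

#' Info-Fraction: the share of target entropy the features carry
#'
#' Computes the kNN mutual information between `X` and `y`, the quantized
#' target entropy, and their ratio clamped to `[0, 1]`. By default the
#' mixed continuous-discrete estimator on the quantized target is used, so
#' numerator and denominator refer to the same discretized variable; the
#' fully continuous Kraskov-type mode is available through `cfg`.
#'
#' @param X Feature matrix or vector.
#' @param y Target vector.
#' @param cfg An [mi_config()].
#' @return An `mi_estimate` with fields `mi`, `target_entropy`,
#'   `info_fraction` (in `[0, 1]`, `NA` with a flag when the target is
#'   degenerate), `n` and `config`.
#' @export
info_fraction <- function(X, y, cfg = mi_config()) {
  d <- drop_missing_rows(X, y)
  mi <- knn_mi(d$X, d$y, cfg)
  H <- target_entropy(d$y, cfg)
  frac <- if (H > 0) clamp(mi / H, 0, 1) else NA_real_
  structure(list(mi = as.numeric(mi), target_entropy = H,
                 info_fraction = frac, n = length(d$y),
                 degenerate_target = H == 0, config = cfg),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> MI %.3f nats, H(target) %.3f nats, Info-Fraction %s (n = %d)\n",
              x$mi, x$target_entropy,
              if (is.na(x$info_fraction)) "undefined (degenerate target)"
              else sprintf("%.1f%%", 100 * x$info_fraction),
              x$n))
  invisible(x)
}
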