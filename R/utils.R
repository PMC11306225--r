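# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Population (divide-by-n) standard deviation; the error-SD convention used
# throughout device-grading literature, and exact on tiny examples.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Piecewise rolling statistic: compute `fun` over consecutive blocks of
# `block` samples and linearly interpolate block centres back to sample
# resolution. Cheap, deterministic stand-in for a full rolling quantile.
block_stat <- function(x, block, fun) {
  n <- length(x)
  block <- max(2L, min(block, n))
  starts <- seq(1L, n, by = block)
  centers <- pmin(starts + (block - 1L) / 2, n)
  vals <- vapply(starts, function(s) fun(x[s:min(s + block - 1L, n)]), 0.0)
  if (length(vals) == 1L) return(rep(vals, n))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
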