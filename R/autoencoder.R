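# A small dense MLP autoencoder featurizer: input -> 128 -> bottleneck ->
# 128 -> input, ReLU hidden activations, linear output, Adam on
# mean-squared error. Implemented directly with matrix operations; training
# is seeded and deterministic.

#' Autoencoder settings
#'
#' @param bottleneck Width of the code layer (default 20).
#' @param hidden Width of the two hidden layers (default 128).
#' @param lr Adam step size (default 0.001).
#' @param loss_tol Stop when the epoch mean-squared error drops below this
#'   (default 0.1, on min-max normalized inputs).
#' @param max_epochs Epoch cap; reaching it without convergence warns but
#'   still returns the encoder.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization and shuffling.
#' @return An `ae_config`.
#' @export
ae_config <- function(bottleneck = 20, hidden = 128, lr = 1e-3,
                      loss_tol = 0.1, max_epochs = 200, batch_size = 64,
                      seed = 0) {
  structure(list(bottleneck = bottleneck, hidden = hidden, lr = lr,
                 loss_tol = loss_tol, max_epochs = max_epochs,
                 batch_size = batch_size, seed = seed),
            class = "ae_config")
}

#' Min-max normalize windows to [0, 1]
#'
#' @param ws A `window_set` or a numeric matrix (rows = windows).
#' @return A matrix with every row scaled to `[0, 1]` (constant rows map
#'   to 0).
#' @export
normalize_unit <- function(ws) {
  X <- if (inherits(ws, "window_set")) ws$values else as.matrix(ws)
  rng <- apply(X, 1L, function(r) diff(range(r)))
  lo <- apply(X, 1L, min)
  X <- sweep(X, 1L, lo)
  X <- sweep(X, 1L, ifelse(rng > 0, rng, 1), "/")
  X
}

#' Fit the MLP autoencoder
#'
#' @param X Matrix of normalized windows (rows in `[0, 1]`), or a
#'   `window_set` (normalized internally).
#' @param cfg An [ae_config()].
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `ppg_autoencoder` holding the weights, the
#'   final training loss and the epoch count.
#' @export
fit_autoencoder <- function(X, cfg = ae_config(), verbose = FALSE) {
  if (inherits(X, "window_set")) X <- normalize_unit(X)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (cfg$bottleneck >= d) stopf("bottleneck must be smaller than the input length")
  with_seed(cfg$seed, {
    sizes <- c(d, cfg$hidden, cfg$bottleneck, cfg$hidden, d)
    W <- lapply(1:4, function(l) matrix(rnorm(sizes[l] * sizes[l + 1L],
                                              sd = sqrt(2 / sizes[l])),
                                        sizes[l], sizes[l + 1L]))
    b <- lapply(1:4, function(l) rep(0, sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    loss <- Inf; epoch <- 0L
    while (epoch < cfg$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- X[rows, , drop = FALSE]
        m <- nrow(xb)
        # forward
        z1 <- sweep(xb %*% W[[1L]], 2L, b[[1L]], "+"); a1 <- pmax(z1, 0)
        z2 <- sweep(a1 %*% W[[2L]], 2L, b[[2L]], "+"); a2 <- pmax(z2, 0)
        z3 <- sweep(a2 %*% W[[3L]], 2L, b[[3L]], "+"); a3 <- pmax(z3, 0)
        out <- sweep(a3 %*% W[[4L]], 2L, b[[4L]], "+")
        err <- out - xb
        batch_losses <- c(batch_losses, mean(err^2))
        # backward (d loss / d out = 2 err / (m*d))
        g <- 2 * err / (m * d)
        gW <- vector("list", 4L); gb <- vector("list", 4L)
        gW[[4L]] <- crossprod(a3, g); gb[[4L]] <- colSums(g)
        g <- (g %*% t(W[[4L]])) * (z3 > 0)
        gW[[3L]] <- crossprod(a2, g); gb[[3L]] <- colSums(g)
        g <- (g %*% t(W[[3L]])) * (z2 > 0)
        gW[[2L]] <- crossprod(a1, g); gb[[2L]] <- colSums(g)
        g <- (g %*% t(W[[2L]])) * (z1 > 0)
        gW[[1L]] <- crossprod(xb, g); gb[[1L]] <- colSums(g)
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in 1:4) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - cfg$lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] - cfg$lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      loss <- mean(batch_losses)
      if (verbose && epoch %% 10L == 0L)
        message(sprintf("epoch %d: loss %.5f", epoch, loss))
      if (loss < cfg$loss_tol) break
    }
    if (loss >= cfg$loss_tol)
      warnf("autoencoder stopped at the epoch cap (%d) with loss %.4f >= %.4f",
            cfg$max_epochs, loss, cfg$loss_tol)
    structure(list(W = W, b = b, final_loss = loss, epochs = epoch, cfg = cfg),
              class = "ppg_autoencoder")
  })
}

#' @export
print.ppg_autoencoder <- function(x, ...) {
  cat(sprintf("<ppg_autoencoder> %d-%d-%d bottleneck; %d epochs, final loss %.4f\n",
              nrow(x$W[[1L]]), ncol(x$W[[1L]]), ncol(x$W[[2L]]),
              x$epochs, x$final_loss))
  invisible(x)
}

#' Encode windows to bottleneck features
#'
#' Deterministic given a fitted encoder.
#'
#' @param encoder A fitted [fit_autoencoder()] object.
#' @param X Matrix of normalized windows or a `window_set`.
#' @return Matrix with `bottleneck` columns, one row per window.
#' @export
encode <- function(encoder, X) {
  if (inherits(X, "window_set")) X <- normalize_unit(X)
  X <- as.matrix(X)
  a1 <- pmax(sweep(X %*% encoder$W[[1L]], 2L, encoder$b[[1L]], "+"), 0)
  pmax(sweep(a1 %*% encoder$W[[2L]], 2L, encoder$b[[2L]], "+"), 0)
}
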