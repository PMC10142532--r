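# Compact multilayer perceptron for the neural adapters: ReLU hidden
# layers, linear output, mean-squared-error loss, Adam updates,
# mini-batches, inverted dropout in every hidden layer.  Pure matrix code
# -- sized for the small tabular problems this package targets, not for
# GPU-scale work.  Targets are standardized internally for stable
# optimization and predictions mapped back to the original scale.

mlp_fit <- function(X, y, hidden = c(128L), dropout_rate = 0.2,
                    epochs = 1000L, batch_size = 32L, learning_rate = 1e-3,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  y_mean <- mean(y); y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  yz <- (y - y_mean) / y_sd

  sizes <- c(p, hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                             sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
    keep <- 1 - dropout_rate

    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1L, n)]
        A <- X[rows, , drop = FALSE]
        acts <- vector("list", L + 1L); acts[[1L]] <- A
        masks <- vector("list", L)
        for (l in seq_len(L)) {
          Z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], `+`)
          if (l < L) {
            A <- pmax(Z, 0)
            if (dropout_rate > 0) {
              m <- matrix(rbinom(length(A), 1L, keep), nrow(A)) / keep
              A <- A * m
              masks[[l]] <- m
            }
          } else {
            A <- Z
          }
          acts[[l + 1L]] <- A
        }
        # backprop, dLoss/dpred for MSE
        delta <- 2 * (acts[[L + 1L]] - yz[rows]) / length(rows)
        t_step <- t_step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            delta <- delta * (acts[[l]] > 0)
            if (dropout_rate > 0) delta <- delta * masks[[l - 1L]]
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mc <- 1 - beta1^t_step; vc <- 1 - beta2^t_step
          W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / mc) /
            (sqrt(vW[[l]] / vc) + eps)
          b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / mc) /
            (sqrt(vb[[l]] / vc) + eps)
        }
      }
    }
  })
  list(W = W, b = b, hidden = hidden, dropout_rate = dropout_rate,
       y_mean = y_mean, y_sd = y_sd, p = p)
}

# one forward pass; when `dropout_rate` > 0 a seeded inverted-dropout
# mask is applied to every hidden layer (the MC-dropout inference path)
mlp_forward <- function(net, X, dropout_rate = 0, mask_seed = NULL) {
  L <- length(net$W)
  run <- function() {
    A <- as.matrix(X)
    keep <- 1 - dropout_rate
    for (l in seq_len(L)) {
      Z <- sweep(A %*% net$W[[l]], 2L, net$b[[l]], `+`)
      if (l < L) {
        A <- pmax(Z, 0)
        if (dropout_rate > 0) {
          m <- matrix(rbinom(length(A), 1L, keep), nrow(A)) / keep
          A <- A * m
        }
      } else {
        A <- Z
      }
    }
    as.numeric(A) * net$y_sd + net$y_mean
  }
  if (dropout_rate > 0 && !is.null(mask_seed)) with_seed(mask_seed, run()) else run()
}
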