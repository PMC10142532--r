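# Instrumented test adapters.  `mock_mean` predicts the training mean and
# counts its fits; `mock_lm` is a deterministic, row-order-insensitive
# ordinary-least-squares learner used for equivariance and noiseless
# recovery checks.

mock_fit_counter <- new.env(parent = emptyenv())
mock_fit_counter$n <- 0L

reset_fit_counter <- function() mock_fit_counter$n <- 0L

register_adapter(
  "mock_mean",
  fit = function(X, y, hp, seed) {
    mock_fit_counter$n <- mock_fit_counter$n + 1L
    list(mean = mean(y))
  },
  predict = function(handle, X) rep(handle$mean, nrow(X))
)

register_adapter(
  "mock_lm",
  fit = function(X, y, hp, seed) {
    Xi <- cbind(1, X)
    list(coef = qr.coef(qr(Xi), y))
  },
  predict = function(handle, X) {
    co <- handle$coef
    co[is.na(co)] <- 0
    as.numeric(cbind(1, X) %*% co)
  }
)

# small deterministic regression dataset with attached features
linear_dataset <- function(n = 60, p = 4, sigma = 0, seed = 42) {
  uqens:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- seq_len(p) / p
    y <- 2 + as.numeric(X %*% beta) + rnorm(n, 0, sigma)
    molecular_dataset(
      ids = sprintf("cmp%03d", seq_len(n)),
      smiles = rep("", n),
      targets = y,
      features = feature_matrix(X, kind = "learned")
    )
  })
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
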