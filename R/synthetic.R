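# Synthetic benchmark generators.  They stand in for curated
# compound-activity collections: feature matrices with latent low-rank
# structure, a smooth nonlinear input-output map, heteroscedastic noise
# with a controllable difficulty knob, duplicate records for the dedup
# path -- plus direct generators for member prediction matrices and
# saturation curves with known ground truth, so the aggregation, metric
# and growth machinery can be tested without fitting a single model.

#' Specification for a synthetic dataset
#'
#' @param n number of unique compounds (>= 10).
#' @param p feature dimension.
#' @param r latent rank (`r <= p`): features are `Z %*% W` with `Z`
#'   standard normal `n x r` and `W` a fixed `r x p` mixing matrix.
#' @param sigma baseline noise standard deviation (target units).
#' @param h heteroscedasticity coefficient: per-compound noise is
#'   `sigma * (1 + h * s)` with difficulty score `s` in `[0, 1]`.
#' @param duplicate_fraction fraction in `[0, 1)` of compounds appearing
#'   a second time with a jittered target (exercises
#'   [deduplicate_and_average()]).
#' @param seed integer seed; generation is a pure function of spec+seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 300L, p = 32L, r = 4L, sigma = 0.3, h = 1,
                           duplicate_fraction = 0, seed = 1L) {
  if (n < 10L) stopf("n must be >= 10")
  if (r > p) stopf("latent rank r = %d exceeds p = %d", r, p)
  if (sigma < 0 || h < 0) stopf("sigma and h must be non-negative")
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    stopf("duplicate_fraction must be in [0, 1)")
  }
  structure(list(n = as.integer(n), p = as.integer(p), r = as.integer(r),
                 sigma = sigma, h = h,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic molecular dataset
#'
#' Latent coordinates `Z` (standard normal) are mixed into `p` observed
#' features; targets follow a smooth sum-of-sigmoids map of the latent
#' coordinates (centered at 6, roughly the scale of log-transformed
#' potencies) plus heteroscedastic Gaussian noise.  The per-compound
#' difficulty score driving the noise level is
#' `s = P(chi^2_r <= ||z||^2)` -- compounds far from the latent center
#' are noisier, mimicking sparsely covered chemistry -- and is stored in
#' `$extra$difficulty` together with the noise-free targets and noise
#' standard deviations.  Compounds carry unique valid SMILES (simple
#' N/O-terminated carbon chains) so the structure-key dedup path is
#' exercised end to end.
#'
#' @param spec a [synthetic_spec()].
#' @return A [molecular_dataset()] with `n * (1 + duplicate_fraction)`
#'   records (duplicates appended with fresh identifiers and jittered
#'   targets) and features of kind `learned` attached.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n; p <- spec$p; r <- spec$r
    W <- matrix(rnorm(r * p), r, p)
    Z <- matrix(rnorm(n * r), n, r)
    X <- Z %*% W
    amp <- (2.5 / sqrt(r)) * rep_len(c(1, -1), r)
    slope <- runif(r, 0.8, 1.5)
    shift <- rnorm(r, 0, 0.5)
    g <- 6 + as.numeric(vapply(seq_len(r), function(j) {
      amp[j] * stats::plogis(slope[j] * Z[, j] + shift[j])
    }, numeric(n)) %*% rep(1, r))
    s <- stats::pchisq(rowSums(Z^2), df = r)
    noise_sd <- spec$sigma * (1 + spec$h * s)
    y <- g + rnorm(n, 0, noise_sd)

    smiles <- synthetic_smiles(n)
    ids <- sprintf("SYN%05d", seq_len(n))
    n_dup <- floor(spec$duplicate_fraction * n)
    if (n_dup > 0L) {
      dup_rows <- sample.int(n, n_dup)
      smiles <- c(smiles, smiles[dup_rows])
      ids <- c(ids, sprintf("SYN%05d", n + seq_len(n_dup)))
      y <- c(y, y[dup_rows] + rnorm(n_dup, 0, 0.1))
      X <- rbind(X, X[dup_rows, , drop = FALSE])
      g <- c(g, g[dup_rows]); s <- c(s, s[dup_rows])
      noise_sd <- c(noise_sd, noise_sd[dup_rows])
    }
    molecular_dataset(
      ids, smiles, y,
      features = feature_matrix(X, kind = "learned",
                                feature_names = paste0("f", seq_len(p))),
      extra = list(difficulty = s, noise_free = g, noise_sd = noise_sd)
    )
  })
}

# unique chain molecules "N C^i O C^j": the distinct terminals orient the
# chain, so distinct (i, j) pairs are distinct structures
synthetic_smiles <- function(n) {
  k <- ceiling(sqrt(n))
  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  vapply(seq_len(n), function(t) {
    paste0("N", strrep("C", grid$i[t]), "O", strrep("C", grid$j[t]))
  }, "")
}

#' Directly synthesize a member prediction matrix with known truth
#'
#' Bypasses model fitting: member predictions are
#' `yhat[i, m] = y[i] + bias[i] + eta[i, m]` with
#' `eta[i, m] ~ N(0, tau[i])`.  Because `bias` and `tau` are stored as
#' ground truth, the behaviour of the ensemble uncertainty is known
#' analytically -- e.g. the population standard deviation over members
#' estimates `tau[i]`, and a dominant constant bias with vanishing `tau`
#' reproduces the regime where ensembles fail entirely: near-zero
#' uncertainties alongside large errors.
#'
#' @param n number of compounds.
#' @param M number of members (>= 2).
#' @param error_model list with entries `y_center` (default 6),
#'   `y_spread` (default 1), `bias_mean` (default 0), `bias_sd`
#'   (default 0), and `tau` (length-2 range; member noise standard
#'   deviations are drawn log-uniformly between the two values; equal
#'   values give a constant spread).
#' @param seed integer seed.
#' @return A `member_matrix` with a `"truth"` attribute carrying
#'   `y`, `bias`, `tau`.
#' @export
make_member_matrix <- function(n, M, error_model = list(), seed = 1L) {
  if (M < 2L) stopf("M must be >= 2")
  em <- utils::modifyList(
    list(y_center = 6, y_spread = 1, bias_mean = 0, bias_sd = 0,
         tau = c(0.1, 1)),
    error_model
  )
  tau_range <- rep_len(as.numeric(em$tau), 2L)
  with_seed(seed, {
    y <- rnorm(n, em$y_center, em$y_spread)
    bias <- rnorm(n, em$bias_mean, em$bias_sd)
    tau <- exp(runif(n, log(max(tau_range[1L], 1e-12)),
                     log(max(tau_range[2L], 1e-12))))
    if (tau_range[1L] == tau_range[2L]) tau <- rep(tau_range[1L], n)
    eta <- matrix(rnorm(n * M, 0, tau), n, M)  # tau recycles down columns
    values <- y + bias + eta
    out <- member_matrix(values, y = y)
    attr(out, "truth") <- list(y = y, bias = bias, tau = tau)
    out
  })
}

#' Synthesize a cumulative curve from a saturation law
#'
#' Samples `f(m) = a + b * m / (c + m)` at sizes `1..M` (optionally
#' `2..M` for rho-style curves) with additive Gaussian noise, attaching
#' the generating parameters as ground truth -- the standard fixture for
#' [fit_saturation()] recovery tests.
#'
#' @param a,b,c Michaelis-Menten parameters (`c > 0`).
#' @param M maximum ensemble size (>= 4).
#' @param sigma noise standard deviation, default 0 (noiseless).
#' @param metric label for the curve, `"r2"` or `"rho"` (sets the
#'   starting size).
#' @param seed integer seed.
#' @return A `cumulative_curve` of variant `permutation_median` with a
#'   `"truth"` attribute `list(a, b, c)`.
#' @export
make_curve <- function(a, b, c, M, sigma = 0, metric = c("r2", "rho"),
                       seed = 1L) {
  metric <- match.arg(metric)
  if (c <= 0) stopf("c must be positive")
  if (M < 4L) stopf("M must be >= 4")
  sizes <- if (metric == "r2") seq_len(M) else 2:M
  values <- a + b * sizes / (c + sizes)
  if (sigma > 0) {
    values <- values + with_seed(seed, rnorm(length(sizes), 0, sigma))
  }
  out <- structure(list(sizes = sizes, values = values, metric = metric,
                        variant = "permutation_median", M = as.integer(M),
                        flag = "ok"),
                   class = "cumulative_curve")
  attr(out, "truth") <- list(a = a, b = b, c = c)
  out
}
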