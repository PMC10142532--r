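#' Cumulative member curve
#'
#' Performance as a function of ensemble size: the value at size `s` is
#' the chosen metric of the ensemble aggregated over the first `s`
#' members in the given order (mean as point estimate; population
#' standard deviation as uncertainty).  Predictive performance (`r2`)
#' starts at size 1, uncertainty performance (`rho`) at size 2, the
#' smallest size with a defined standard deviation.
#'
#' @param mpm a `member_matrix`.
#' @param metric `"r2"` or `"rho"`.
#' @param member_order permutation of `1..M` giving the accumulation
#'   order; default the original member order.
#' @return A `cumulative_curve` with fields `sizes`, `values`, `metric`,
#'   `variant = "raw"`.  A `rho` curve whose uncertainties are
#'   everywhere zero-variance is returned with `NA` values and flagged
#'   `"flat"` via the `flag` field.
#' @export
cumulative_curve <- function(mpm, metric = c("r2", "rho"),
                             member_order = NULL) {
  stopifnot(inherits(mpm, "member_matrix"))
  metric <- match.arg(metric)
  member_order <- member_order %||% seq_len(mpm$M)
  if (length(member_order) != mpm$M ||
      !setequal(member_order, seq_len(mpm$M))) {
    stopf("member_order must be a permutation of 1..%d", mpm$M)
  }
  if (metric == "rho" && mpm$M < 2L) {
    stopf("rho curves need at least 2 members")
  }
  sizes <- if (metric == "r2") seq_len(mpm$M) else 2:mpm$M
  values <- curve_values(mpm, metric, member_order, sizes)
  flag <- if (metric == "rho" && all(is.na(values))) "flat" else "ok"
  structure(list(sizes = sizes, values = values, metric = metric,
                 variant = "raw", M = mpm$M, flag = flag),
            class = "cumulative_curve")
}

# incremental pass over members: running masked sums and sums of squares
# give the ensemble mean/std at every prefix size in O(n * M)
curve_values <- function(mpm, metric, member_order, sizes) {
  n <- mpm$n
  y <- mpm$y
  s1 <- numeric(n); s2 <- numeric(n); cnt <- numeric(n)
  out <- rep(NA_real_, length(sizes))
  size_at <- match(seq_len(mpm$M), sizes)
  for (s in seq_len(mpm$M)) {
    m <- member_order[s]
    keep <- mpm$mask[, m]
    v <- ifelse(keep, mpm$values[, m], 0)
    v[is.na(v)] <- 0
    s1 <- s1 + v
    s2 <- s2 + v^2
    cnt <- cnt + keep
    pos <- size_at[s]
    if (is.na(pos)) next
    yhat <- ifelse(cnt >= 1, s1 / cnt, NA_real_)
    ok <- !is.na(yhat)
    if (metric == "r2") {
      if (sum(ok) >= 2L && length(unique(y[ok])) > 1L) {
        out[pos] <- r_squared(y[ok], yhat[ok])
      }
    } else {
      # clamp cancellation residue so truly identical members report an
      # exactly zero spread (and hence a tied, flagged rho)
      vr <- s2 / cnt - yhat^2
      vr[vr < (s2 / cnt) * 1e-13] <- 0
      u <- ifelse(cnt >= 2, sqrt(pmax(vr, 0)), NA_real_)
      oku <- ok & !is.na(u)
      if (sum(oku) >= 3L) {
        rho <- uq_spearman(u[oku], abs(yhat - y)[oku])
        out[pos] <- as.numeric(rho)
      }
    }
  }
  out
}

#' Permutation-smoothed cumulative member curve
#'
#' Cumulative curves depend on the arbitrary order in which members were
#' generated.  To remove that bias and smooth the curve, the members are
#' shuffled `n_permutations` times, a cumulative curve computed for each
#' order, and the per-size median (default; the mean by option) taken
#' across permutations.  By construction the value at the full size `M`
#' equals the raw full-ensemble value for every seed.
#'
#' @inheritParams cumulative_curve
#' @param n_permutations number of random member orders, default 200.
#' @param seed integer seed for the shuffles.
#' @param center `"median"` or `"mean"` across permutations.
#' @return A `cumulative_curve` with `variant = "permutation_median"`
#'   (or `"permutation_mean"`).
#' @export
permutation_median_curve <- function(mpm, metric = c("r2", "rho"),
                                     n_permutations = 200L, seed = 1L,
                                     center = c("median", "mean")) {
  stopifnot(inherits(mpm, "member_matrix"))
  metric <- match.arg(metric)
  center <- match.arg(center)
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  sizes <- if (metric == "r2") seq_len(mpm$M) else 2:mpm$M
  mat <- matrix(NA_real_, length(sizes), n_permutations)
  for (perm in seq_len(n_permutations)) {
    ord <- with_seed(child_seed(seed, perm), sample.int(mpm$M))
    mat[, perm] <- curve_values(mpm, metric, ord, sizes)
  }
  centre_fn <- if (center == "median") {
    function(row) median(row, na.rm = TRUE)
  } else {
    function(row) mean(row, na.rm = TRUE)
  }
  values <- apply(mat, 1L, centre_fn)
  values[is.nan(values)] <- NA_real_
  flag <- if (all(is.na(values))) "flat" else "ok"
  structure(list(sizes = sizes, values = values, metric = metric,
                 variant = if (center == "median") "permutation_median"
                           else "permutation_mean",
                 M = mpm$M, n_permutations = n_permutations, flag = flag),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("<cumulative_curve> %s, %s, sizes %d..%d\n",
              x$metric, x$variant, min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Michaelis-Menten saturation fit and minimal ensemble size
#'
#' Fits `f(m) = a + b * m / (c + m)` to a (smoothed) cumulative member
#' curve by least squares and reads off the saturation size: the first
#' integer step of the fitted curve whose member-to-member gain
#' `f(m + 1) - f(m)` falls below `gain_threshold` (default 1e-4, i.e.
#' the point where further members change at most the fourth decimal
#' place).  The offset `a` is required because cumulative curves start
#' at the nonzero single-model performance.  For `b > 0, c > 0` the
#' step gains are strictly decreasing in `m`, so the first crossing is
#' unique.
#'
#' The fit profiles the residual sum of squares over `c` (the model is
#' linear in `a` and `b` given `c`), which is robust for noiseless and
#' flat curves alike, and polishes the optimum on a log grid.
#'
#' @param curve a `cumulative_curve`, normally of variant
#'   `permutation_median`, with at least 4 finite points.
#' @param gain_threshold saturation gain threshold, default `1e-4`.
#' @return A `saturation_fit` with parameters `a`, `b`, `c`, the
#'   residual sum of squares, the detected size `m_star` (or `NULL` when
#'   none is detected inside the observed range), and a quality flag in
#'   `"ok"`, `"flat"`, `"noisy"`, `"decreasing"`.
#' @export
fit_saturation <- function(curve, gain_threshold = 1e-4) {
  stopifnot(inherits(curve, "cumulative_curve"))
  ok <- is.finite(curve$values)
  m <- curve$sizes[ok]
  v <- curve$values[ok]
  if (length(m) < 4L) stopf("need at least 4 finite curve points")

  rss_at <- function(cc) {
    x <- m / (cc + m)
    fit <- stats::.lm.fit(cbind(1, x), v)
    sum(fit$residuals^2)
  }
  log_grid <- seq(log(1e-3), log(100 * max(m)), length.out = 120L)
  rss <- vapply(exp(log_grid), rss_at, 0)
  i <- which.min(rss)
  lo <- log_grid[max(1L, i - 1L)]
  hi <- log_grid[min(length(log_grid), i + 1L)]
  opt <- optimize(function(lc) rss_at(exp(lc)), c(lo, hi), tol = 1e-12)
  c_hat <- exp(opt$minimum)
  coefs <- stats::.lm.fit(cbind(1, m / (c_hat + m)), v)$coefficients
  a_hat <- coefs[1L]; b_hat <- coefs[2L]
  residual <- rss_at(c_hat)

  span <- diff(range(v))
  flag <- "ok"
  if (abs(b_hat) < gain_threshold) {
    flag <- "flat"
  } else if (b_hat < 0) {
    flag <- "decreasing"
  } else if (span > 0 && residual / length(v) > (0.25 * span)^2) {
    flag <- "noisy"  # RMS residual above a quarter of the curve's span
  }

  m_star <- NULL
  if (flag %in% c("ok", "flat")) {
    steps <- seq.int(min(m), max(m) - 1L)
    gains <- b_hat * c_hat / ((c_hat + steps) * (c_hat + steps + 1))
    hit <- which(gains < gain_threshold)
    if (length(hit) > 0L) m_star <- as.integer(steps[hit[1L]])
  }
  structure(list(a = unname(a_hat), b = unname(b_hat), c = unname(c_hat),
                 residual = residual, m_star = m_star, flag = flag,
                 metric = curve$metric, gain_threshold = gain_threshold),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "<saturation_fit> a = %.4g, b = %.4g, c = %.4g, flag = %s, m* = %s\n",
    x$a, x$b, x$c, x$flag,
    if (is.null(x$m_star)) "none detected" else x$m_star))
  invisible(x)
}

#' Summarize saturation sizes across datasets and combinations
#'
#' Per group (e.g. featurization-by-technique combination), the median
#' detected saturation size, excluding fits where none was detected;
#' exclusion counts are reported.  Non-integer medians occur naturally
#' for even group sizes.
#'
#' @param fits list of `saturation_fit` objects.
#' @param groups character vector assigning each fit to a group.
#' @return Data frame with `group`, `median_m_star`, `n_detected`,
#'   `n_excluded`.  Groups whose fits all lack a saturation size are
#'   reported with `NA` median rather than raising an error.
#' @export
summarize_saturation <- function(fits, groups = rep("all", length(fits))) {
  stopifnot(length(fits) == length(groups))
  split_idx <- split(seq_along(fits), groups)
  rows <- lapply(names(split_idx), function(g) {
    ms <- unlist(lapply(fits[split_idx[[g]]], function(f) f$m_star))
    data.frame(group = g,
               median_m_star = if (length(ms) > 0L) median(ms) else NA_real_,
               n_detected = length(ms),
               n_excluded = length(split_idx[[g]]) - length(ms))
  })
  do.call(rbind, rows)
}
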