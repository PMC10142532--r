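#' Aggregate member predictions into an ensemble result
#'
#' Collapses a member prediction matrix into the ensemble point estimate
#' (the arithmetic mean of the retained member predictions per compound)
#' and the ensemble uncertainty (their population standard deviation,
#' i.e. divisor equal to the retained member count, not count minus
#' one).  Masked entries are excluded, with the per-compound divisor
#' replaced by the retained count: the outlier filter eliminates
#' predictions, not compounds.
#'
#' @param x a `member_matrix`.
#' @param subset member (column) indices to aggregate, default all.
#' @param sample_sd if `TRUE`, use the sample standard deviation
#'   (divisor count - 1) instead of the population form.
#' @param ... unused.
#' @return An `ensemble_result`: per compound the point estimate `yhat`,
#'   uncertainty `uncertainty`, observed `y`, `abs_error` and
#'   `n_members_retained`.  Compounds with fewer than 2 retained members
#'   get `NA` uncertainty; with 0 retained members both are `NA`.
#' @export
#' @method aggregate member_matrix
aggregate.member_matrix <- function(x, subset = NULL, sample_sd = FALSE,
                                    ...) {
  subset <- subset %||% seq_len(x$M)
  if (length(subset) < 1L) stopf("subset must contain at least one member")
  if (any(subset < 1L | subset > x$M)) stopf("subset out of range 1..%d", x$M)
  v <- x$values[, subset, drop = FALSE]
  keep <- x$mask[, subset, drop = FALSE]
  v[!keep] <- NA_real_
  cnt <- rowSums(keep)
  s1 <- rowSums(v, na.rm = TRUE)
  yhat <- ifelse(cnt >= 1L, s1 / cnt, NA_real_)
  # two-pass form of the population variance: numerically exact where the
  # one-pass sum-of-squares form loses digits to cancellation; identical
  # members must report exactly zero spread, so rounding residue (order
  # eps^2 relative to the mean) is clamped away
  var_pop <- rowSums((v - yhat)^2, na.rm = TRUE) / cnt
  var_pop[var_pop < yhat^2 * 1e-28] <- 0
  u <- ifelse(cnt >= 2L,
              if (sample_sd) sqrt(var_pop * cnt / (cnt - 1L)) else sqrt(var_pop),
              NA_real_)
  structure(
    list(ids = x$ids, y = x$y, yhat = yhat, uncertainty = u,
         abs_error = abs(yhat - x$y), n_members_retained = as.integer(cnt),
         n = x$n, M_used = length(subset)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %d compounds, %d members used; %d compound(s) missing\n",
    x$n, x$M_used, sum(is.na(x$yhat))))
  invisible(x)
}

#' @export
as.data.frame.ensemble_result <- function(x, ...) {
  data.frame(id = x$ids, y = x$y, yhat = x$yhat,
             uncertainty = x$uncertainty, abs_error = x$abs_error,
             n_members_retained = x$n_members_retained)
}

#' Score an ensemble result
#'
#' Dataset-level quality pair: predictive performance as the
#' cross-validated coefficient of determination [r_squared()] and
#' uncertainty-quantification performance as the Spearman correlation
#' [uq_spearman()] between uncertainty and absolute error.  Compounds
#' with missing point estimate (resp. uncertainty) are excluded
#' pairwise, with the evaluated count reported.
#'
#' @param res an `ensemble_result`.
#' @return List with `r2`, `rho`, `n_r2`, `n_rho`.
#' @export
performance_pair <- function(res) {
  stopifnot(inherits(res, "ensemble_result"))
  ok_pred <- !is.na(res$yhat)
  r2 <- r_squared(res$y[ok_pred], res$yhat[ok_pred])
  ok_u <- ok_pred & !is.na(res$uncertainty)
  rho <- if (sum(ok_u) >= 3L) {
    uq_spearman(res$uncertainty[ok_u], res$abs_error[ok_u])
  } else {
    NA_real_
  }
  list(r2 = r2, rho = as.numeric(rho), n_r2 = sum(ok_pred), n_rho = sum(ok_u))
}
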