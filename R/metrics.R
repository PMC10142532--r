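#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: the cross-validated
#' R-squared when `yhat` are out-of-sample predictions.  A relative
#' metric comparable across datasets; it becomes negative when the
#' prediction error sum of squares exceeds the total sum of squares.
#'
#' @param y observed values (length >= 2, not constant).
#' @param yhat predicted values, same length.
#' @return A real number `<= 1`.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("y and yhat differ in length")
  if (length(y) < 2L) stopf("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("R-squared undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Spearman correlation between uncertainty and absolute error
#'
#' Measures how well the uncertainty values rank the predictions by the
#' magnitude of their error: Pearson's correlation computed on average
#' ranks (ties receive the mean of their rank range).  1 is a perfect
#' ranking, -1 a perfect anti-ranking; for good models even ideal
#' uncertainties yield values well below 1 because realized errors are
#' noisy draws.  Pairs with a missing uncertainty are excluded.
#'
#' @param uncertainties non-negative uncertainty values.
#' @param abs_errors absolute prediction errors, same length.
#' @return Spearman's rho, or `NA` with a `"diagnostic"` attribute when
#'   one input is completely tied (all-equal spreads make ranking
#'   impossible -- the degenerate scenario this metric is designed to
#'   expose).
#' @export
uq_spearman <- function(uncertainties, abs_errors) {
  if (length(uncertainties) != length(abs_errors)) {
    stopf("inputs differ in length")
  }
  ok <- !is.na(uncertainties) & !is.na(abs_errors)
  u <- uncertainties[ok]; e <- abs_errors[ok]
  if (length(u) < 3L) stopf("need at least 3 complete pairs")
  if (length(unique(u)) == 1L || length(unique(e)) == 1L) {
    out <- NA_real_
    attr(out, "diagnostic") <- "all values tied; rank correlation undefined"
    return(out)
  }
  cor(rank(u, ties.method = "average"), rank(e, ties.method = "average"),
      method = "pearson")
}

#' Rank sums across a performance grid
#'
#' Within every dataset (row), the competing featurization-by-technique
#' combinations (columns) are ranked -- rank 1 for the best value, ties
#' receiving average ranks -- and each combination's ranks are summed
#' over datasets.  Lower rank sums indicate consistently better
#' combinations.  Without ties the grand total of all rank sums is
#' `D * C * (C + 1) / 2` for `D` datasets and `C` combinations.
#'
#' @param performance numeric matrix, datasets x combinations, complete
#'   (any `NA` cell is an error naming the cell).
#' @param direction `"higher_is_better"` (R-squared, rho) or
#'   `"lower_is_better"`.
#' @return A `rank_sum_table`: the per-dataset `ranks` matrix and the
#'   named `rank_sums` vector.
#' @export
rank_sums <- function(performance, direction = c("higher_is_better",
                                                 "lower_is_better")) {
  direction <- match.arg(direction)
  performance <- as.matrix(performance)
  if (is.null(colnames(performance))) {
    colnames(performance) <- paste0("combo_", seq_len(ncol(performance)))
  }
  if (is.null(rownames(performance))) {
    rownames(performance) <- paste0("dataset_", seq_len(nrow(performance)))
  }
  na_cells <- which(is.na(performance), arr.ind = TRUE)
  if (nrow(na_cells) > 0L) {
    stopf("incomplete performance grid: missing %s",
          paste(sprintf("(%s, %s)", rownames(performance)[na_cells[, 1L]],
                        colnames(performance)[na_cells[, 2L]]),
                collapse = ", "))
  }
  rank_row <- function(row) {
    if (direction == "higher_is_better") {
      rank(-row, ties.method = "average")
    } else {
      rank(row, ties.method = "average")
    }
  }
  ranks <- do.call(rbind, lapply(seq_len(nrow(performance)), function(i) {
    rank_row(performance[i, ])
  }))
  dimnames(ranks) <- dimnames(performance)
  sums <- colSums(ranks)
  structure(list(ranks = ranks, rank_sums = sums,
                 direction = direction,
                 n_datasets = nrow(performance),
                 n_combinations = ncol(performance)),
            class = "rank_sum_table")
}

#' @export
print.rank_sum_table <- function(x, ...) {
  cat(sprintf("<rank_sum_table> %d datasets x %d combinations\n",
              x$n_datasets, x$n_combinations))
  print(sort(x$rank_sums))
  invisible(x)
}

#' Reshape rank sums into a techniques-by-featurizations table
#'
#' Convenience layout for grids whose combination names follow
#' `"<featurization>.<technique>"`: rows are techniques, columns
#' featurizations, matching the usual heatmap presentation.
#'
#' @param x a `rank_sum_table`.
#' @return A numeric matrix, or the plain rank-sum vector when the names
#'   do not parse.
#' @export
rank_sum_grid <- function(x) {
  stopifnot(inherits(x, "rank_sum_table"))
  parts <- strsplit(names(x$rank_sums), ".", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 2L)) return(x$rank_sums)
  feat <- vapply(parts, `[`, "", 1L)
  tech <- vapply(parts, `[`, "", 2L)
  out <- matrix(NA_real_, length(unique(tech)), length(unique(feat)),
                dimnames = list(unique(tech), unique(feat)))
  for (i in seq_along(x$rank_sums)) out[tech[i], feat[i]] <- x$rank_sums[i]
  out
}
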