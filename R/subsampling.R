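#' Plan the subsampling splits for an ensemble
#'
#' For the k-fold scheme, each of the `M` repetitions is an independent
#' random partition of the `n` compounds into `k` folds whose sizes
#' differ by at most one -- a balanced scheme in which every compound is
#' out-of-sample exactly once per repetition.  For the bootstrap scheme,
#' each member trains on `n` draws with replacement and is evaluated on
#' its out-of-bag compounds.  Plans depend only on `n` and the seed
#' (label-blind) and are reproducible.
#'
#' @param n number of compounds.
#' @param scheme `"kfold"` or `"bootstrap"`.
#' @param k number of folds (k-fold scheme), default 2: small enough for
#'   diverse members, large enough training halves for reasonable models.
#' @param M number of ensemble members (repetitions), default 200.
#' @param seed integer seed.
#' @return A `split_plan`; for k-fold it carries `folds`, an `n x M`
#'   integer matrix of fold assignments, for bootstrap `inbag`, an
#'   `n x M` count matrix of training draws.
#' @export
make_split_plan <- function(n, scheme = c("kfold", "bootstrap"), k = 2L,
                            M = 200L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- as.integer(n); k <- as.integer(k); M <- as.integer(M)
  if (M < 1L) stopf("M must be >= 1")
  if (scheme == "kfold") {
    if (k < 2L) stopf("k must be >= 2")
    if (n < k) stopf("n = %d is smaller than k = %d", n, k)
    folds <- with_seed(seed, {
      vapply(seq_len(M), function(m) {
        # shuffle, then deal indices into folds round-robin: balanced by
        # construction (sizes differ by <= 1)
        assignment <- integer(n)
        assignment[sample.int(n)] <- rep_len(seq_len(k), n)
        assignment
      }, integer(n))
    })
    folds <- matrix(folds, nrow = n)
    structure(list(scheme = "kfold", n = n, k = k, M = M, seed = seed,
                   folds = folds),
              class = "split_plan")
  } else {
    if (n < 2L) stopf("n must be >= 2")
    inbag <- with_seed(seed, {
      vapply(seq_len(M), function(m) {
        tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      }, integer(n))
    })
    inbag <- matrix(inbag, nrow = n)
    structure(list(scheme = "bootstrap", n = n, k = 1L, M = M, seed = seed,
                   inbag = inbag),
              class = "split_plan")
  }
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, n = %d, k = %d, M = %d (%d model fits)\n",
              x$scheme, x$n, x$k, x$M, x$M * x$k))
  invisible(x)
}

#' Number of model fits a plan implies
#' @param plan a `split_plan`.
#' @return `M * k` for k-fold, `M` for bootstrap.
#' @export
n_fits <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  if (plan$scheme == "kfold") plan$M * plan$k else plan$M
}

#' Member prediction matrix constructor
#'
#' The central intermediate of the pipeline: one column of out-of-sample
#' predictions per ensemble member, plus a same-shape retention mask and
#' the training-target range of the model behind every entry (needed by
#' the prediction-outlier filter).
#'
#' @param values n x M numeric matrix; entries not predicted by a member
#'   (bootstrap in-bag) are `NA`.
#' @param y observed targets, length n.
#' @param ids compound identifiers, length n.
#' @param ymin,ymax n x M matrices of the training-target range of the
#'   model that produced each entry (`NA` where undefined).
#' @param mask logical n x M matrix of retained entries; defaults to the
#'   defined entries.
#' @return A `member_matrix`.
#' @export
member_matrix <- function(values, y, ids = NULL, ymin = NULL, ymax = NULL,
                          mask = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); M <- ncol(values)
  if (length(y) != n) stopf("y has length %d for %d rows", length(y), n)
  if (is.null(mask)) mask <- !is.na(values)
  structure(list(values = values, mask = mask, y = as.numeric(y),
                 ids = ids %||% as.character(seq_len(n)),
                 ymin = ymin, ymax = ymax, n = n, M = M),
            class = "member_matrix")
}

#' @export
print.member_matrix <- function(x, ...) {
  cat(sprintf(
    "<member_matrix> %d compounds x %d members; %.1f%% entries retained\n",
    x$n, x$M, 100 * mean(x$mask)))
  invisible(x)
}

#' Fit all ensemble members and collect out-of-sample predictions
#'
#' Executes a [make_split_plan()]: for every repetition, one model per
#' training partition is fitted (with a feature scaler fitted on that
#' training partition only and applied to both partitions) and each
#' compound's prediction is taken from the model whose test fold
#' contained it.  One ensemble member is one full repetition -- the k
#' fold models jointly covering all compounds -- so a k-fold plan with M
#' repetitions costs `M * k` fits.  Each member fit derives its own
#' child seed from the spec seed and the repetition index, making
#' results independent of scheduling.
#'
#' @param ds a [molecular_dataset()] with features attached (a
#'   [feature_matrix()] or plain matrix, treated as kind `learned`).
#' @param spec a [regressor_spec()].
#' @param plan a `split_plan` with `plan$n == n_compounds(ds)`.
#' @param continue_on_error if `TRUE`, a failing member fit masks its
#'   entries and is recorded in the `failures` attribute instead of
#'   aborting.
#' @return A `member_matrix` with training ranges recorded and an
#'   `n_fits` attribute counting the model fits performed.
#' @export
run_members <- function(ds, spec, plan, continue_on_error = FALSE) {
  stopifnot(inherits(ds, "molecular_dataset"), inherits(plan, "split_plan"))
  n <- n_compounds(ds)
  if (plan$n != n) stopf("plan built for n = %d, dataset has %d", plan$n, n)
  if (is.null(ds$features)) stopf("dataset has no features; featurize first")
  fm <- ds$features
  if (!inherits(fm, "feature_matrix")) {
    fm <- feature_matrix(fm, kind = "learned")
  }
  y <- ds$targets
  values <- matrix(NA_real_, n, plan$M)
  ymin <- matrix(NA_real_, n, plan$M)
  ymax <- matrix(NA_real_, n, plan$M)
  fits_done <- 0L
  failures <- list()

  fit_and_fill <- function(train_idx, test_idx, m, member_seed) {
    scaler <- fit_scaler(fm[train_idx, , drop = FALSE])
    Xtr <- apply_scaler(fm[train_idx, , drop = FALSE], scaler)
    Xte <- apply_scaler(fm[test_idx, , drop = FALSE], scaler)
    member_spec <- regressor_spec(spec$technique, spec$hyperparameters,
                                  seed = member_seed)
    model <- fit_model(member_spec, unclass(Xtr), y[train_idx])
    fits_done <<- fits_done + 1L
    values[test_idx, m] <<- predict(model, unclass(Xte))
    ymin[test_idx, m] <<- model$y_range[1L]
    ymax[test_idx, m] <<- model$y_range[2L]
  }

  for (m in seq_len(plan$M)) {
    run_one <- function() {
      if (plan$scheme == "kfold") {
        assignment <- plan$folds[, m]
        for (f in seq_len(plan$k)) {
          fit_and_fill(which(assignment != f), which(assignment == f), m,
                       child_seed(spec$seed, (m - 1L) * plan$k + f))
        }
      } else {
        counts <- plan$inbag[, m]
        train_idx <- rep(seq_len(n), counts)
        test_idx <- which(counts == 0L)
        if (length(test_idx) > 0L) {
          fit_and_fill(train_idx, test_idx, m, child_seed(spec$seed, m))
        }
      }
    }
    if (continue_on_error) {
      tryCatch(run_one(), error = function(e) {
        failures[[length(failures) + 1L]] <<-
          list(member = m, message = conditionMessage(e))
        values[, m] <<- NA_real_
      })
    } else {
      tryCatch(run_one(), error = function(e) {
        stopf("member %d (technique '%s') failed: %s",
              m, spec$technique, conditionMessage(e))
      })
    }
  }

  out <- member_matrix(values, y = y, ids = ds$ids, ymin = ymin, ymax = ymax)
  attr(out, "n_fits") <- fits_done
  attr(out, "failures") <- failures
  out
}

#' Eliminate predictions outside twice the training output range
#'
#' Masks every member prediction lying outside the closed interval of
#' width `2 * (y_max - y_min)` centered on the training-target range of
#' the model that produced it, i.e. outside
#' `[y_min - w/2, y_max + w/2]` with `w = y_max - y_min`.  This guards
#' downstream aggregation against the occasional wildly extrapolated
#' prediction (a known hazard for neural networks fed descriptors with
#' extreme values).  The mask is monotone: already-masked entries are
#' never unmasked.  With a degenerate training range (`w = 0`), only
#' predictions equal to the training constant are retained.
#'
#' @param mpm a `member_matrix` with training ranges recorded.
#' @return The filtered `member_matrix`; compounds that lost all their
#'   members are listed in the `"all_masked"` attribute.
#' @export
filter_outlier_predictions <- function(mpm) {
  stopifnot(inherits(mpm, "member_matrix"))
  if (is.null(mpm$ymin) || is.null(mpm$ymax)) {
    stopf("member matrix carries no training ranges")
  }
  w <- mpm$ymax - mpm$ymin
  lo <- mpm$ymin - w / 2
  hi <- mpm$ymax + w / 2
  inside <- !is.na(mpm$values) & mpm$values >= lo & mpm$values <= hi
  mpm$mask <- mpm$mask & inside
  all_masked <- which(rowSums(mpm$mask) == 0L)
  attr(mpm, "all_masked") <- all_masked
  mpm
}
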