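#' Configuration of a benchmark run
#'
#' Describes the full grid: datasets (paths with column maps, in-memory
#' [molecular_dataset()]s, or [synthetic_spec()]s), featurizations,
#' modeling techniques, the subsampling scheme and the analysis toggles.
#'
#' @param datasets named list; each element is a `molecular_dataset`, a
#'   `synthetic_spec`, or a list with `path` (+ optional `column_map`,
#'   `features_path`) for [load_dataset()].
#' @param featurizations subset of `"maccs"`, `"morgan_counts"`,
#'   `"physchem"`, `"precomputed"`.
#' @param techniques subset of the registered techniques
#'   (see [list_adapters()]).
#' @param scheme,k,M subsampling scheme passed to [make_split_plan()].
#' @param seed integer master seed; every cell derives child seeds.
#' @param growth run the growing-ensemble analysis per cell.
#' @param n_permutations member-order shuffles for the growth analysis.
#' @param continue_on_error record failing cells instead of aborting the
#'   grid (an unsuccessful ensemble is a result, not a crash).
#' @param output_dir optional directory for result artifacts; member
#'   matrices are cached there keyed by a configuration hash and reused
#'   when the configuration matches.
#' @return A `run_config`.
#' @export
run_config <- function(datasets, featurizations = "precomputed",
                       techniques = c("rf", "xgb", "svm"),
                       scheme = "kfold", k = 2L, M = 200L, seed = 1L,
                       growth = TRUE, n_permutations = 200L,
                       continue_on_error = TRUE, output_dir = NULL) {
  if (length(datasets) == 0L) stopf("config needs at least one dataset")
  if (length(featurizations) == 0L) stopf("config needs >= 1 featurization")
  if (length(techniques) == 0L) stopf("config needs >= 1 technique")
  known_feat <- c("maccs", "morgan_counts", "physchem", "precomputed")
  bad <- setdiff(featurizations, known_feat)
  if (length(bad) > 0L) stopf("unknown featurization(s): %s",
                              paste(bad, collapse = ", "))
  for (t in techniques) get_adapter(t)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset_", seq_along(datasets))
  }
  for (d in datasets) {
    if (is.list(d) && !is.null(d$path) && !inherits(d, "synthetic_spec") &&
        !inherits(d, "molecular_dataset") && !file.exists(d$path)) {
      stopf("dataset path does not exist: %s", d$path)
    }
  }
  cfg <- structure(
    list(datasets = datasets, featurizations = featurizations,
         techniques = techniques, scheme = scheme, k = as.integer(k),
         M = as.integer(M), seed = as.integer(seed), growth = growth,
         n_permutations = as.integer(n_permutations),
         continue_on_error = continue_on_error, output_dir = output_dir),
    class = "run_config"
  )
  cfg$hash <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  fields <- cfg[c("featurizations", "techniques", "scheme", "k", "M",
                  "seed")]
  fields$dataset_names <- names(cfg$datasets)
  rlang::hash(fields)
}

#' Enumerate the combination grid of a configuration
#'
#' Cartesian product of datasets, featurizations and techniques in
#' deterministic dataset-major order (dataset varies slowest, technique
#' fastest).
#'
#' @param cfg a [run_config()].
#' @return Data frame with columns `dataset`, `featurization`,
#'   `technique`; one row per combination.
#' @export
enumerate_grid <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  grid <- expand.grid(technique = cfg$techniques,
                      featurization = cfg$featurizations,
                      dataset = names(cfg$datasets),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("dataset", "featurization", "technique")]
}

resolve_dataset <- function(entry) {
  if (inherits(entry, "molecular_dataset")) return(entry)
  if (inherits(entry, "synthetic_spec")) return(make_dataset(entry))
  if (is.list(entry) && !is.null(entry$path)) {
    return(load_dataset(entry$path,
                        column_map = entry$column_map %||%
                          list(id_col = "id", smiles_col = "smiles",
                               target_col = "target"),
                        features_path = entry$features_path))
  }
  stopf("cannot interpret dataset entry of class %s",
        paste(class(entry), collapse = "/"))
}

featurize_dataset <- function(ds, featurization) {
  if (featurization == "precomputed") {
    if (is.null(ds$features)) stopf("no precomputed features attached")
    return(ds)
  }
  if (!all(nzchar(ds$smiles))) {
    stopf("featurization '%s' needs SMILES for every record", featurization)
  }
  ds$features <- switch(featurization,
    maccs = maccs_counts(ds$smiles),
    morgan_counts = morgan_counts(ds$smiles),
    physchem = physchem_descriptors(ds$smiles),
    stopf("unknown featurization '%s'", featurization)
  )
  ds
}

#' Run the full benchmark grid
#'
#' For every (dataset, featurization, technique) cell: deduplicate,
#' featurize, plan the subsampling, fit all members, filter outlier
#' predictions, aggregate, and score.  Optionally runs the
#' growing-ensemble analysis per cell.  Cells whose ensembles fail
#' (errors, flat or decreasing curves) are recorded with their flag and
#' never abort the grid when `continue_on_error` is set -- validating
#' the success of an ensemble is part of the result.
#'
#' @param cfg a [run_config()].
#' @param progress print one line per cell.
#' @return A `study_result`: `cells` (per-cell list with performance,
#'   optional saturation fits, timing), `performance` (data frame), and
#'   rank-sum tables for both metrics when the grid is complete.
#' @export
run_study <- function(cfg, progress = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  grid <- enumerate_grid(cfg)
  cells <- vector("list", nrow(grid))
  cache_dir <- NULL
  if (!is.null(cfg$output_dir)) {
    cache_dir <- file.path(cfg$output_dir, cfg$hash)
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  datasets <- lapply(cfg$datasets, function(entry) {
    deduplicate_and_average(resolve_dataset(entry))
  })
  feat_cache <- new.env(parent = emptyenv())
  featurized <- function(dataset, featurization) {
    key <- paste(dataset, featurization, sep = "\r")
    if (!exists(key, envir = feat_cache, inherits = FALSE)) {
      assign(key, featurize_dataset(datasets[[dataset]], featurization),
             envir = feat_cache)
    }
    get(key, envir = feat_cache, inherits = FALSE)
  }
  for (row in seq_len(nrow(grid))) {
    cell <- as.list(grid[row, ])
    t0 <- proc.time()[["elapsed"]]
    outcome <- tryCatch({
      ds <- featurized(cell$dataset, cell$featurization)
      cell_seed <- child_seed(cfg$seed, row)
      plan <- make_split_plan(n_compounds(ds), scheme = cfg$scheme,
                              k = cfg$k, M = cfg$M, seed = cell_seed)
      spec <- regressor_spec(cell$technique, seed = cell_seed)
      mpm <- run_members(ds, spec, plan,
                         continue_on_error = cfg$continue_on_error)
      mpm <- filter_outlier_predictions(mpm)
      res <- aggregate(mpm)
      perf <- performance_pair(res)
      out <- list(result = res, r2 = perf$r2, rho = perf$rho,
                  n_fits = attr(mpm, "n_fits"), status = "ok")
      if (isTRUE(cfg$growth)) {
        out$growth <- lapply(setNames(, c("r2", "rho")), function(metric) {
          curve <- permutation_median_curve(
            mpm, metric = metric, n_permutations = cfg$n_permutations,
            seed = child_seed(cfg$seed, row + 100000L))
          fit <- if (sum(is.finite(curve$values)) >= 4L) {
            fit_saturation(curve)
          } else {
            structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                           residual = NA_real_, m_star = NULL,
                           flag = curve$flag, metric = metric),
                      class = "saturation_fit")
          }
          list(curve = curve, fit = fit)
        })
      }
      if (!is.null(cache_dir)) {
        stem <- file.path(cache_dir, paste(cell$dataset, cell$featurization,
                                           cell$technique, sep = "__"))
        write_results(res, paste0(stem, ".csv"))
      }
      out
    }, error = function(e) {
      if (!cfg$continue_on_error) stop(e)
      list(result = NULL, r2 = NA_real_, rho = NA_real_,
           n_fits = NA_integer_, status = paste("error:",
                                                conditionMessage(e)))
    })
    outcome$elapsed <- proc.time()[["elapsed"]] - t0
    cells[[row]] <- c(cell, outcome)
    if (isTRUE(progress)) {
      message(sprintf("[%d/%d] %s | %s | %s: R2 = %.3f, rho = %.3f (%.1fs)",
                      row, nrow(grid), cell$dataset, cell$featurization,
                      cell$technique, outcome$r2, outcome$rho,
                      outcome$elapsed))
    }
  }
  performance <- data.frame(
    grid,
    r2 = vapply(cells, function(cl) cl$r2, 0),
    rho = vapply(cells, function(cl) cl$rho, 0),
    status = vapply(cells, function(cl) cl$status, "")
  )
  out <- list(cells = cells, performance = performance, config = cfg)
  combo <- paste(performance$featurization, performance$technique, sep = ".")
  if (!anyNA(performance$r2)) {
    out$rank_sums_r2 <- rank_sums(
      perf_matrix(performance$dataset, combo, performance$r2))
  }
  if (!anyNA(performance$rho)) {
    out$rank_sums_rho <- rank_sums(
      perf_matrix(performance$dataset, combo, performance$rho))
  }
  structure(out, class = "study_result")
}

perf_matrix <- function(dataset, combo, value) {
  ds <- unique(dataset); cb <- unique(combo)
  m <- matrix(NA_real_, length(ds), length(cb), dimnames = list(ds, cb))
  for (i in seq_along(value)) m[dataset[i], combo[i]] <- value[i]
  m
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d cells (%d ok)\n",
              nrow(x$performance), sum(x$performance$status == "ok")))
  print(x$performance[, c("dataset", "featurization", "technique",
                          "r2", "rho")])
  invisible(x)
}

#' Single-model baseline with built-in uncertainty
#'
#' The reference point the subsampling ensemble is benchmarked against:
#' one k-fold cross-validation (default 10-fold) producing exactly one
#' out-of-sample prediction per compound, with the technique's built-in
#' uncertainty -- per-tree spread for random forests, MC dropout for the
#' networks -- evaluated by the same metrics as the ensembles.
#'
#' @param ds a [molecular_dataset()] with features attached.
#' @param spec a [regressor_spec()] whose technique has an internal UQ
#'   capability (`"rf"`, `"snn"`, `"dnn"`).
#' @param folds number of CV folds, default 10.
#' @param seed integer seed.
#' @param n_passes MC-dropout passes (network techniques), default 100.
#' @return An `ensemble_result`-shaped baseline (uncertainty from the
#'   built-in mechanism, `n_members_retained = 1`).
#' @export
run_single_model_baseline <- function(ds, spec, folds = 10L, seed = 1L,
                                      n_passes = 100L) {
  stopifnot(inherits(ds, "molecular_dataset"),
            inherits(spec, "regressor_spec"))
  adapter <- get_adapter(spec$technique)
  if (adapter$internal_uq == "none") {
    stopf("technique '%s' has no built-in uncertainty mechanism",
          spec$technique)
  }
  if (is.null(ds$features)) stopf("dataset has no features; featurize first")
  fm <- ds$features
  if (!inherits(fm, "feature_matrix")) fm <- feature_matrix(fm, "learned")
  n <- n_compounds(ds)
  plan <- make_split_plan(n, scheme = "kfold", k = folds, M = 1L,
                          seed = seed)
  assignment <- plan$folds[, 1L]
  yhat <- rep(NA_real_, n); u <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    train_idx <- which(assignment != f)
    test_idx <- which(assignment == f)
    if (length(test_idx) == 0L) next
    scaler <- fit_scaler(fm[train_idx, , drop = FALSE])
    Xtr <- unclass(apply_scaler(fm[train_idx, , drop = FALSE], scaler))
    Xte <- unclass(apply_scaler(fm[test_idx, , drop = FALSE], scaler))
    model <- fit_model(regressor_spec(spec$technique, spec$hyperparameters,
                                      seed = child_seed(seed, f)),
                       Xtr, ds$targets[train_idx])
    res <- if (adapter$internal_uq == "tree_variance") {
      rf_internal_uq(model, Xte)
    } else {
      mc_dropout_uq(model, Xte, n_passes = n_passes,
                    seed = child_seed(seed, 1000L + f))
    }
    yhat[test_idx] <- res$prediction
    u[test_idx] <- res$uncertainty
  }
  structure(
    list(ids = ds$ids, y = ds$targets, yhat = yhat, uncertainty = u,
         abs_error = abs(yhat - ds$targets),
         n_members_retained = rep(1L, n), n = n, M_used = 1L),
    class = "ensemble_result"
  )
}

#' Pairwise comparison of ensemble and baseline results
#'
#' Per case (matched by name) the differences in predictive and
#' uncertainty performance, win counts and median absolute differences
#' -- the direct-comparison summary used to decide whether the ensemble
#' machinery pays off over the built-in mechanism.
#'
#' @param ensemble named list of `ensemble_result`s.
#' @param baseline named list of `ensemble_result`s for the same cases.
#' @return List with a per-case data frame (`delta_r2`, `delta_rho`;
#'   positive favors the ensemble), win counts and median `|delta|`s.
#' @export
compare_ensemble_vs_baseline <- function(ensemble, baseline) {
  missing_b <- setdiff(names(ensemble), names(baseline))
  missing_e <- setdiff(names(baseline), names(ensemble))
  if (length(missing_b) > 0L || length(missing_e) > 0L) {
    stopf("mismatched case sets: only in ensemble: {%s}; only in baseline: {%s}",
          paste(missing_b, collapse = ", "),
          paste(missing_e, collapse = ", "))
  }
  cases <- names(ensemble)
  rows <- lapply(cases, function(case) {
    pe <- performance_pair(ensemble[[case]])
    pb <- performance_pair(baseline[[case]])
    data.frame(case = case, r2_ensemble = pe$r2, r2_baseline = pb$r2,
               delta_r2 = pe$r2 - pb$r2,
               rho_ensemble = pe$rho, rho_baseline = pb$rho,
               delta_rho = pe$rho - pb$rho)
  })
  tab <- do.call(rbind, rows)
  list(
    table = tab,
    wins_r2 = c(ensemble = sum(tab$delta_r2 > 0, na.rm = TRUE),
                baseline = sum(tab$delta_r2 < 0, na.rm = TRUE)),
    wins_rho = c(ensemble = sum(tab$delta_rho > 0, na.rm = TRUE),
                 baseline = sum(tab$delta_rho < 0, na.rm = TRUE)),
    median_abs_delta_r2 = median(abs(tab$delta_r2), na.rm = TRUE),
    median_abs_delta_rho = median(abs(tab$delta_rho), na.rm = TRUE)
  )
}
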