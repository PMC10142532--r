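small_cfg <- function(n_datasets = 2, M = 4, techniques = "mock_lm",
                      growth = FALSE, seed = 1) {
  datasets <- lapply(seq_len(n_datasets), function(i) {
    synthetic_spec(n = 40, p = 6, r = 2, sigma = 0.2, seed = 100 + i)
  })
  names(datasets) <- paste0("synth", seq_len(n_datasets))
  run_config(datasets, featurizations = "precomputed",
             techniques = techniques, k = 2, M = M, seed = seed,
             growth = growth, n_permutations = 10)
}

test_that("the combination grid is the dataset-major Cartesian product", {
  cfg <- small_cfg()
  cfg$featurizations <- c("precomputed", "morgan_counts")
  cfg$techniques <- c("rf", "svm")
  grid <- enumerate_grid(cfg)
  expect_equal(nrow(grid), 2 * 2 * 2)
  expect_equal(grid$dataset[1:4], rep("synth1", 4))
  expect_equal(grid$technique[1:2], c("rf", "svm"))

  one <- small_cfg(n_datasets = 1, techniques = "rf")
  expect_equal(nrow(enumerate_grid(one)), 1L)
})

test_that("config validation rejects empty or unknown selections", {
  expect_error(small_cfg(techniques = character(0)), ">= 1 technique")
  expect_error(small_cfg(techniques = "hal9000"), "unknown")
  cfg <- small_cfg()
  cfg$featurizations <- "quantum"
  expect_error(run_config(cfg$datasets, "quantum", "rf"), "featurization")
})

test_that("run_study completes a small grid and scores every cell", {
  cfg <- small_cfg(n_datasets = 2, M = 4, growth = TRUE)
  study <- run_study(cfg, progress = FALSE)
  expect_equal(nrow(study$performance), 2L)
  expect_true(all(study$performance$status == "ok"))
  expect_true(all(is.finite(study$performance$r2)))
  for (cell in study$cells) {
    expect_equal(cell$n_fits, 8L)  # M * k
    expect_true(!is.null(cell$growth$r2$fit$flag))
    g <- cell$growth$rho$fit
    expect_true(is.integer(g$m_star) || is.null(g$m_star))
  }
  expect_s3_class(study$rank_sums_r2, "rank_sum_table")
})

test_that("failed cells are recorded without aborting the grid", {
  register_adapter("mock_fragile", fit = function(X, y, hp, seed) {
    stop("cannot fit")
  }, predict = function(h, X) rep(0, nrow(X)))
  cfg <- small_cfg(n_datasets = 1, techniques = c("mock_lm", "mock_fragile"))
  study <- run_study(cfg, progress = FALSE)
  status <- study$performance$status
  expect_equal(sum(status == "ok"), 1L)
  expect_match(status[status != "ok"], "error")
  expect_null(study$rank_sums_r2)  # incomplete grid: no rank sums
})

test_that("member caches land under the configuration hash", {
  out <- tempfile()
  cfg <- small_cfg(n_datasets = 1)
  cfg$output_dir <- out
  study <- run_study(cfg, progress = FALSE)
  files <- list.files(file.path(out, cfg$hash))
  expect_true(length(files) >= 1)
})

test_that("the single-model baseline covers every compound once", {
  ds <- make_dataset(synthetic_spec(n = 60, p = 8, r = 2, sigma = 0.2,
                                    seed = 5))
  base <- run_single_model_baseline(ds, regressor_spec("rf"), folds = 10,
                                    seed = 2)
  expect_equal(sum(!is.na(base$yhat)), 60L)
  expect_true(all(base$uncertainty >= 0))
  expect_equal(base$n_members_retained, rep(1L, 60))
  expect_error(run_single_model_baseline(ds, regressor_spec("svm")),
               "built-in")
  # deterministic given the seed
  base2 <- run_single_model_baseline(ds, regressor_spec("rf"), folds = 10,
                                     seed = 2)
  expect_identical(base$yhat, base2$yhat)
})

test_that("ten folds on ten compounds degenerate to leave-one-out", {
  ds <- make_dataset(synthetic_spec(n = 10, p = 4, r = 2, sigma = 0.1,
                                    seed = 6))
  plan <- make_split_plan(10, "kfold", k = 10, M = 1, seed = 1)
  expect_true(all(table(plan$folds[, 1]) == 1))
  base <- run_single_model_baseline(ds, regressor_spec("rf"), folds = 10,
                                    seed = 3)
  expect_equal(sum(!is.na(base$yhat)), 10L)
})

test_that("ensemble-vs-baseline comparisons count wins and medians", {
  mm <- make_member_matrix(30, 6, seed = 2)
  res <- aggregate(mm)
  # identical inputs: all deltas zero
  cmp <- compare_ensemble_vs_baseline(list(a = res, b = res),
                                      list(a = res, b = res))
  expect_equal(cmp$table$delta_r2, c(0, 0))
  expect_equal(cmp$median_abs_delta_rho, 0)
  # one case each way
  better <- res; better$yhat <- res$y; better$abs_error <- rep(0, 30)
  cmp2 <- compare_ensemble_vs_baseline(list(a = better, b = res),
                                       list(a = res, b = better))
  expect_equal(unname(cmp2$wins_r2), c(1, 1))
  expect_error(compare_ensemble_vs_baseline(list(a = res), list(b = res)),
               "mismatched")
})

test_that("rf ensembles and single rf baselines score comparably", {
  deltas <- vapply(1:3, function(s) {
    ds <- make_dataset(synthetic_spec(n = 200, p = 10, r = 3, sigma = 0.25,
                                      seed = 400 + s))
    plan <- make_split_plan(200, "kfold", k = 2, M = 10,
                            seed = uqens:::child_seed(s, 1))
    mpm <- filter_outlier_predictions(
      run_members(ds, regressor_spec("rf", seed = s), plan))
    ens <- performance_pair(aggregate(mpm))$r2
    bas <- performance_pair(
      run_single_model_baseline(ds, regressor_spec("rf"), folds = 10,
                                seed = s))$r2
    ens - bas
  }, 0)
  expect_lt(median(abs(deltas)), 0.1)
})
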