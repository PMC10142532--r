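test_that("k-fold plans are balanced and reproducible", {
  p <- make_split_plan(10, "kfold", k = 2, M = 1, seed = 1)
  sizes <- table(p$folds[, 1])
  expect_equal(sort(as.numeric(sizes)), c(5, 5))
  expect_equal(sort(unique(p$folds[, 1])), 1:2)

  p11 <- make_split_plan(11, "kfold", k = 2, M = 3, seed = 1)
  for (m in 1:3) {
    expect_equal(sort(as.numeric(table(p11$folds[, m]))), c(5, 6))
  }

  a <- make_split_plan(50, "kfold", k = 5, M = 4, seed = 99)
  b <- make_split_plan(50, "kfold", k = 5, M = 4, seed = 99)
  expect_identical(a$folds, b$folds)
  expect_false(identical(
    a$folds, make_split_plan(50, "kfold", k = 5, M = 4, seed = 100)$folds))
  expect_error(make_split_plan(3, "kfold", k = 5), "smaller than")
})

test_that("every compound is out-of-sample exactly once per repetition", {
  for (cfg in list(c(n = 37, k = 2, M = 8), c(n = 100, k = 10, M = 5))) {
    p <- make_split_plan(cfg["n"], "kfold", k = cfg["k"], M = cfg["M"],
                         seed = 3)
    for (m in seq_len(cfg["M"])) {
      assignment <- p$folds[, m]
      # each index sits in exactly one fold; union of test folds is 1..n
      expect_equal(length(assignment), as.integer(cfg["n"]))
      expect_true(all(assignment %in% seq_len(cfg["k"])))
    }
  }
})

test_that("plans are label-blind", {
  # the plan is a function of (n, scheme, k, M, seed) only; there is no
  # argument through which targets could leak, and equal inputs give
  # equal plans
  expect_identical(make_split_plan(40, "kfold", k = 4, M = 2, seed = 5),
                   make_split_plan(40, "kfold", k = 4, M = 2, seed = 5))
})

test_that("bootstrap members leave about 1/e of compounds out of bag", {
  p <- make_split_plan(500, "bootstrap", M = 60, seed = 8)
  oob_frac <- mean(p$inbag == 0)
  expect_equal(oob_frac, exp(-1), tolerance = 0.05)
  # every member trains on exactly n draws
  expect_true(all(colSums(p$inbag) == 500))
})

test_that("run_members performs exactly M*k fits and fills every entry", {
  ds <- linear_dataset(n = 40)
  plan <- make_split_plan(40, "kfold", k = 2, M = 3, seed = 2)
  reset_fit_counter()
  mpm <- run_members(ds, regressor_spec("mock_mean"), plan)
  expect_equal(mock_fit_counter$n, 6L)
  expect_equal(attr(mpm, "n_fits"), 6L)
  expect_equal(n_fits(plan), 6L)
  # k-fold pre-filter: every compound has exactly M defined entries
  expect_true(all(rowSums(!is.na(mpm$values)) == 3L))
  expect_true(all(rowSums(mpm$mask) == 3L))
})

test_that("an exact learner predicts noiseless linear data out of sample", {
  ds <- linear_dataset(n = 50, sigma = 0)
  plan <- make_split_plan(50, "kfold", k = 2, M = 1, seed = 6)
  mpm <- run_members(ds, regressor_spec("mock_lm"), plan)
  expect_lt(max(abs(mpm$values[, 1] - ds$targets)), 1e-8)
})

test_that("member predictions are equivariant to compound order", {
  ds <- linear_dataset(n = 30, sigma = 0.1)
  plan <- make_split_plan(30, "kfold", k = 2, M = 2, seed = 4)
  mpm <- run_members(ds, regressor_spec("mock_lm"), plan)

  perm <- uqens:::with_seed(10, sample.int(30))
  ds_p <- molecular_dataset(ds$ids[perm], ds$smiles[perm],
                            ds$targets[perm],
                            features = ds$features[perm, ])
  plan_p <- plan
  plan_p$folds <- plan$folds[perm, , drop = FALSE]
  mpm_p <- run_members(ds_p, regressor_spec("mock_lm"), plan_p)
  expect_equal(mpm_p$values, mpm$values[perm, ], tolerance = 1e-9)
})

test_that("the outlier filter applies the doubled, centered training range", {
  values <- matrix(c(16, 15, 14, -5, -5.01, 7), ncol = 1)
  mm <- member_matrix(values, y = rep(5, 6),
                      ymin = matrix(0, 6, 1), ymax = matrix(10, 6, 1))
  out <- filter_outlier_predictions(mm)
  # training range [0, 10], width 10 -> acceptance interval [-5, 15]
  expect_equal(as.logical(out$mask),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  # with a single member, a filtered prediction leaves its compound bare
  expect_equal(attr(out, "all_masked"), c(1L, 5L))
})

test_that("a degenerate training range only retains the training constant", {
  values <- matrix(c(3, 3.0001, 2.999), ncol = 1)
  mm <- member_matrix(values, y = rep(3, 3),
                      ymin = matrix(3, 3, 1), ymax = matrix(3, 3, 1))
  out <- filter_outlier_predictions(mm)
  expect_equal(as.logical(out$mask), c(TRUE, FALSE, FALSE))
  expect_equal(attr(out, "all_masked"), c(2L, 3L))
})

test_that("the outlier mask is monotone", {
  set.seed(21)
  values <- matrix(rnorm(40, 5, 4), 10, 4)
  mm <- member_matrix(values, y = rep(5, 10),
                      ymin = matrix(4, 10, 4), ymax = matrix(6, 10, 4))
  mm$mask[1, 1] <- FALSE  # pre-masked entry must stay masked
  out <- filter_outlier_predictions(mm)
  expect_false(out$mask[1, 1])
  expect_true(all(out$mask <= mm$mask))
  out2 <- filter_outlier_predictions(out)
  expect_identical(out2$mask, out$mask)
})

test_that("failing member fits abort with context or are recorded", {
  register_adapter("mock_fail", fit = function(X, y, hp, seed) {
    stop("boom")
  }, predict = function(h, X) rep(0, nrow(X)))
  ds <- linear_dataset(n = 20)
  plan <- make_split_plan(20, "kfold", k = 2, M = 2, seed = 1)
  expect_error(run_members(ds, regressor_spec("mock_fail"), plan),
               "member 1")
  mpm <- run_members(ds, regressor_spec("mock_fail"), plan,
                     continue_on_error = TRUE)
  expect_equal(length(attr(mpm, "failures")), 2L)
  expect_true(all(is.na(mpm$values)))
})
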