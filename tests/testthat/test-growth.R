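test_that("cumulative curves start at the documented sizes", {
  mm <- make_member_matrix(40, 10, seed = 5)
  r2c <- cumulative_curve(mm, "r2")
  rhoc <- cumulative_curve(mm, "rho")
  expect_equal(r2c$sizes, 1:10)
  expect_equal(rhoc$sizes, 2:10)
  # base case: size-1 value is the plain single-member R2
  expect_equal(r2c$values[1], r_squared(mm$y, mm$values[, 1]))
  expect_error(cumulative_curve(mm, "r2", member_order = c(1, 1, 2:9)),
               "permutation")
})

test_that("the full-size value is invariant to member order", {
  mm <- make_member_matrix(30, 8, seed = 2)
  full <- tail(cumulative_curve(mm, "r2")$values, 1)
  for (s in 1:5) {
    ord <- uqens:::with_seed(s, sample.int(8))
    expect_equal(tail(cumulative_curve(mm, "r2", member_order = ord)$values,
                      1),
                 full, tolerance = 1e-12)
  }
})

test_that("identical member columns give a flat r2 curve and flagged rho", {
  values <- matrix(rep(rnorm(25, 5), 6), 25, 6)
  mm <- member_matrix(values, y = values[, 1] + rnorm(25, 0, 0.2))
  r2c <- cumulative_curve(mm, "r2")
  expect_true(all(abs(diff(r2c$values)) < 1e-12))
  rhoc <- cumulative_curve(mm, "rho")
  expect_identical(rhoc$flag, "flat")
  expect_true(all(is.na(rhoc$values)))
})

test_that("a single permutation reproduces its raw cumulative curve", {
  mm <- make_member_matrix(30, 7, seed = 6)
  smoothed <- permutation_median_curve(mm, "r2", n_permutations = 1,
                                       seed = 42)
  ord <- uqens:::with_seed(uqens:::child_seed(42, 1), sample.int(7))
  raw <- cumulative_curve(mm, "r2", member_order = ord)
  expect_equal(smoothed$values, raw$values)
  expect_identical(smoothed$variant, "permutation_median")
})

test_that("the smoothed curve ends at the full-ensemble value for any seed", {
  mm <- make_member_matrix(40, 9, seed = 3)
  pp <- performance_pair(aggregate(mm))
  for (s in c(1, 7, 99)) {
    pm <- permutation_median_curve(mm, "rho", n_permutations = 20, seed = s)
    expect_equal(tail(pm$values, 1), pp$rho, tolerance = 1e-12)
  }
})

test_that("exchangeable members produce a statistically flat median curve", {
  # iid member columns: no ordering signal, so the smoothed r2 curve may
  # rise with size (variance averaging) but its tail must be level
  mm <- make_member_matrix(150, 30, list(tau = c(0.4, 0.4)), seed = 9)
  pm <- permutation_median_curve(mm, "r2", n_permutations = 60, seed = 4)
  late <- pm$values[pm$sizes >= 15]
  slope <- coef(lm(late ~ seq_along(late)))[2]
  expect_lt(abs(slope), 5e-4)
})

test_that("saturation fits recover noiseless parameters and the crossing", {
  curve <- make_curve(a = 0.5, b = 0.3, c = 5, M = 200)
  fit <- fit_saturation(curve)
  expect_equal(fit$a, 0.5, tolerance = 1e-6)
  expect_equal(fit$b, 0.3, tolerance = 1e-6)
  expect_equal(fit$c, 5, tolerance = 1e-6)
  # analytic first size where b*c/((c+m)(c+m+1)) < 1e-4
  expect_equal(fit$m_star, 117L)
  expect_identical(fit$flag, "ok")
})

test_that("step gains of a rising fit decrease strictly, making m* unique", {
  fit <- fit_saturation(make_curve(0.2, 0.5, 12, M = 300))
  steps <- 1:299
  gains <- fit$b * fit$c / ((fit$c + steps) * (fit$c + steps + 1))
  expect_true(all(diff(gains) < 0))
  crossings <- which(gains < fit$gain_threshold)
  expect_equal(fit$m_star, as.integer(crossings[1]))
})

test_that("flat and decreasing curves are flagged", {
  flat <- make_curve(0.6, 0, 5, M = 50)
  flat$values <- rep(0.6, 50)
  ffit <- fit_saturation(flat)
  expect_identical(ffit$flag, "flat")
  expect_equal(ffit$m_star, 1L)  # saturated from the first evaluable step

  dec <- make_curve(0.8, -0.3, 10, M = 50)
  dfit <- fit_saturation(dec)
  expect_identical(dfit$flag, "decreasing")
  expect_null(dfit$m_star)

  expect_s3_class(fit_saturation(make_curve(0.5, 0.3, 5, M = 4)),
                  "saturation_fit")  # boundary length accepted
  short <- make_curve(0.5, 0.3, 5, M = 5)
  short$values[1:2] <- NA
  expect_error(fit_saturation(short), "4 finite")
})

test_that("parameter bias shrinks as curve noise vanishes", {
  err_at <- function(sigma) {
    errs <- vapply(1:10, function(s) {
      fit <- fit_saturation(make_curve(0.5, 0.3, 5, M = 200, sigma = sigma,
                                       seed = s))
      abs(fit$c - 5)
    }, 0)
    median(errs)
  }
  expect_lt(err_at(0.001), err_at(0.05))
})

test_that("saturation summaries take per-group medians of detected sizes", {
  fits <- list(
    structure(list(m_star = 10L, flag = "ok"), class = "saturation_fit"),
    structure(list(m_star = 20L, flag = "ok"), class = "saturation_fit"),
    structure(list(m_star = 30L, flag = "ok"), class = "saturation_fit"),
    structure(list(m_star = NULL, flag = "decreasing"),
              class = "saturation_fit"),
    structure(list(m_star = 10L, flag = "ok"), class = "saturation_fit"),
    structure(list(m_star = 20L, flag = "ok"), class = "saturation_fit")
  )
  groups <- c("g1", "g1", "g1", "g2", "g2", "g2")
  s <- summarize_saturation(fits, groups)
  expect_equal(s$median_m_star[s$group == "g1"], 20)
  # even count: half-integer medians are legitimate
  expect_equal(s$median_m_star[s$group == "g2"], 15)
  expect_equal(s$n_excluded[s$group == "g2"], 1L)
  # a group with no detected saturation reports empty, not an error
  s2 <- summarize_saturation(fits[4], "lonely")
  expect_true(is.na(s2$median_m_star))
  expect_equal(s2$n_detected, 0L)
})
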