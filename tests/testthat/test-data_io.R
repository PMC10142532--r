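test_that("load_dataset reads a table preserving order and typing", {
  path <- write_temp_csv(data.frame(
    id = c("a", "b", "c"),
    smiles = c("CCO", "CCC", "c1ccccc1"),
    target = c(5.1, 6.2, 7.3)
  ))
  ds <- load_dataset(path)
  expect_s3_class(ds, "molecular_dataset")
  expect_equal(n_compounds(ds), 3L)
  expect_equal(ds$ids, c("a", "b", "c"))
  expect_equal(ds$targets, c(5.1, 6.2, 7.3))
})

test_that("load_dataset supports custom column maps and TSV", {
  df <- data.frame(chembl_id = c("x", "y"), smi = c("C", "CC"),
                   pIC50 = c(4, 8))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- load_dataset(path, column_map = list(id_col = "chembl_id",
                                             smiles_col = "smi",
                                             target_col = "pIC50"))
  expect_equal(ds$smiles, c("C", "CC"))
  expect_equal(ds$targets, c(4, 8))
})

test_that("load_dataset errors name the failing row or column", {
  path <- write_temp_csv(data.frame(
    id = c("a", "b", "c"), smiles = c("C", "C", "C"),
    target = c("1.5", "not_a_number", "2.5")
  ))
  expect_error(load_dataset(path), "row 2")

  path2 <- write_temp_csv(data.frame(id = "a", value = 1))
  expect_error(load_dataset(path2), "missing column")

  empty <- tempfile(fileext = ".csv")
  writeLines("id,smiles,target", empty)
  expect_error(load_dataset(empty), "no records")
})

test_that("precomputed feature matrices attach without a SMILES column", {
  tab <- write_temp_csv(data.frame(id = c("a", "b"), target = c(1, 2)))
  feats <- write_temp_csv(data.frame(f1 = c(0.1, 0.2), f2 = c(-1, 1)))
  ds <- load_dataset(tab, column_map = list(id_col = "id",
                                            target_col = "target"),
                     features_path = feats)
  expect_equal(dim(ds$features), c(2L, 2L))
  expect_equal(ds$smiles, c("", ""))
})

test_that("deduplication averages targets and keeps the first identifier", {
  # CCO and OCC are the same structure written in different atom orders
  ds <- molecular_dataset(ids = c("A", "B"), smiles = c("CCO", "OCC"),
                          targets = c(4, 6))
  out <- deduplicate_and_average(ds)
  expect_equal(n_compounds(out), 1L)
  expect_equal(out$ids, "A")
  expect_equal(out$targets, 5.0)

  ds3 <- molecular_dataset(ids = c("A", "B", "C"),
                           smiles = rep("CCN", 3), targets = c(1, 2, 6))
  expect_equal(deduplicate_and_average(ds3)$targets, 3.0)
})

test_that("deduplication is an identity on distinct structures and idempotent", {
  ds <- molecular_dataset(ids = c("A", "B", "C"),
                          smiles = c("C", "CC", "CCC"),
                          targets = c(1, 2, 3))
  out <- deduplicate_and_average(ds)
  expect_equal(out$ids, ds$ids)
  expect_equal(out$targets, ds$targets)

  dup <- molecular_dataset(ids = c("A", "B", "C", "D"),
                           smiles = c("CCO", "CC", "OCC", "CC"),
                           targets = c(1, 10, 3, 20))
  once <- deduplicate_and_average(dup)
  twice <- deduplicate_and_average(once)
  expect_equal(once$ids, twice$ids)
  expect_equal(once$targets, twice$targets)
})

test_that("dedup conserves the group-size-weighted sum of targets", {
  set.seed(11)
  base <- c("C", "CC", "CCC", "CCO", "CCN")
  idx <- sample(1:5, 40, replace = TRUE)
  ds <- molecular_dataset(ids = sprintf("id%02d", 1:40),
                          smiles = base[idx],
                          targets = rnorm(40, 6))
  out <- deduplicate_and_average(ds)
  sizes <- as.numeric(table(idx)[as.character(
    match(out$smiles, base))])
  expect_equal(sum(out$targets * sizes), sum(ds$targets))
})

test_that("result writers round-trip values at full precision", {
  mm <- make_member_matrix(8, 5, seed = 2)
  res <- aggregate(mm)
  csv <- tempfile(fileext = ".csv")
  write_results(res, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$yhat, res$yhat, tolerance = 0)
  expect_equal(back$uncertainty, res$uncertainty, tolerance = 0)
  expect_equal(nrow(back), mm$n)

  curve <- make_curve(0.4, 0.2, 8, M = 30)
  fit <- fit_saturation(curve)
  js <- tempfile(fileext = ".json")
  write_results(fit, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$a, fit$a, tolerance = 0)
  expect_equal(parsed$c, fit$c, tolerance = 0)
  expect_equal(parsed$m_star, fit$m_star)

  ccsv <- tempfile(fileext = ".csv")
  write_results(curve, ccsv)
  cb <- utils::read.csv(ccsv)
  expect_equal(cb$value, curve$values, tolerance = 0)
  expect_equal(cb$size, curve$sizes)
})

test_that("member matrices cache to CSV plus sidecar and reload exactly", {
  mm <- make_member_matrix(6, 4, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_results(mm, path)
  wide <- utils::read.csv(path, check.names = FALSE)
  expect_equal(unname(as.matrix(wide[, -1])), mm$values, tolerance = 0)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_equal(meta$y, mm$y, tolerance = 0)
})
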