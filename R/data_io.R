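#' Construct a molecular dataset
#'
#' Container for a compound-target table: identifiers, SMILES, an optional
#' feature matrix and the numeric target vector (assay values, typically
#' log-transformed upstream).
#'
#' @param ids character vector of compound identifiers.
#' @param smiles character vector of SMILES strings; may be empty strings
#'   when precomputed features are supplied instead (learned
#'   representations such as CDDD).
#' @param targets numeric vector of target values, finite.
#' @param features optional numeric matrix with one row per compound
#'   (precomputed features), or a [feature_matrix()].
#' @param extra optional named list of additional per-compound columns
#'   (e.g. the difficulty score attached by [make_dataset()]).
#' @return An object of class `molecular_dataset`.
#' @export
molecular_dataset <- function(ids, smiles, targets, features = NULL,
                              extra = list()) {
  n <- length(ids)
  if (length(smiles) != n || length(targets) != n) {
    stopf("ids, smiles and targets must have equal length")
  }
  if (!is.numeric(targets) || any(!is.finite(targets))) {
    stopf("targets must be finite numbers")
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) {
      stopf("feature matrix has %d rows for %d compounds", nrow(features), n)
    }
  }
  structure(
    list(ids = as.character(ids), smiles = as.character(smiles),
         targets = as.numeric(targets), features = features, extra = extra),
    class = "molecular_dataset"
  )
}

#' @export
print.molecular_dataset <- function(x, ...) {
  cat(sprintf("<molecular_dataset> %d compounds", length(x$ids)))
  if (!is.null(x$features)) {
    cat(sprintf(", %d features", ncol(x$features)))
  }
  cat(sprintf("; target range [%.3g, %.3g]\n",
              min(x$targets), max(x$targets)))
  invisible(x)
}

#' Number of compounds in a dataset
#' @param x a `molecular_dataset`.
#' @export
n_compounds <- function(x) length(x$ids)

#' Load a compound-target table
#'
#' Reads a CSV/TSV file with a header into a [molecular_dataset()].  The
#' column mapping names the identifier, SMILES and target columns; a
#' precomputed feature matrix (CSV, one row per compound, same order) can
#' be attached for learned representations, in which case the SMILES
#' column may be omitted and the records carry empty SMILES.
#'
#' @param path path to the table file (`.csv` or `.tsv`/`.txt`).
#' @param column_map named list with entries `id_col`, `smiles_col`
#'   (optional when `features_path` is given) and `target_col`.
#' @param features_path optional path to a CSV feature matrix.
#' @return A `molecular_dataset` with one record per row, input order
#'   preserved.
#' @export
load_dataset <- function(path,
                         column_map = list(id_col = "id",
                                           smiles_col = "smiles",
                                           target_col = "target"),
                         features_path = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read_table_auto(path)
  if (nrow(tab) == 0L) stopf("no records in %s", path)
  id_col <- column_map$id_col %||% "id"
  target_col <- column_map$target_col %||% "target"
  smiles_col <- column_map$smiles_col
  needed <- c(id_col, target_col, if (is.null(features_path)) smiles_col)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stopf("missing column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  raw_target <- tab[[target_col]]
  target <- suppressWarnings(as.numeric(raw_target))
  bad <- which(is.na(target) | !is.finite(target))
  if (length(bad) > 0L) {
    stopf("unparsable target value in row %s of %s",
          paste(bad, collapse = ", "), path)
  }
  smiles <- if (!is.null(smiles_col) && smiles_col %in% names(tab)) {
    as.character(tab[[smiles_col]])
  } else {
    rep("", nrow(tab))
  }
  features <- NULL
  if (!is.null(features_path)) {
    if (!file.exists(features_path)) {
      stopf("feature file not found: %s", features_path)
    }
    features <- as.matrix(read_table_auto(features_path))
    storage.mode(features) <- "double"
    if (nrow(features) != nrow(tab)) {
      stopf("feature matrix has %d rows for %d records",
            nrow(features), nrow(tab))
    }
  }
  molecular_dataset(tab[[id_col]], smiles, target, features)
}

read_table_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Merge duplicate structures by averaging their targets
#'
#' Compounds are grouped by canonical structure (canonical SMILES from the
#' chemistry toolkit, or the raw identifier when no SMILES are present).
#' Each structure is kept once, in first-appearance order, with the
#' arithmetic mean of its group's targets and the first identifier in
#' input order.  Rows of an attached feature matrix follow the kept
#' record.  The operation is idempotent.
#'
#' @param ds a [molecular_dataset()].
#' @return A deduplicated `molecular_dataset`.
#' @export
deduplicate_and_average <- function(ds) {
  stopifnot(inherits(ds, "molecular_dataset"))
  n <- n_compounds(ds)
  if (n == 0L) return(ds)
  key <- if (all(nzchar(ds$smiles))) {
    canonical_smiles(ds$smiles)
  } else {
    ds$ids
  }
  first_idx <- which(!duplicated(key))
  group <- match(key, key[first_idx])
  mean_target <- as.numeric(tapply(ds$targets, group, mean))
  out <- molecular_dataset(
    ids = ds$ids[first_idx],
    smiles = ds$smiles[first_idx],
    targets = mean_target,
    features = if (!is.null(ds$features)) {
      ds$features[first_idx, , drop = FALSE]
    },
    extra = lapply(ds$extra, function(col) col[first_idx])
  )
  out
}

#' Write a result object to disk
#'
#' Serializes the package's result types to CSV or JSON such that reading
#' the file back reconstructs the stored values to full double precision
#' (JSON numbers are written with 17 significant digits).
#'
#' @param x a result object (`ensemble_result`, `saturation_fit`,
#'   `cumulative_curve`, `member_matrix`, `rank_sum_table`, or a plain
#'   data.frame).
#' @param path destination file path.
#' @param format `"csv"` or `"json"`; the default picks by extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.default <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  df <- as.data.frame(x)
  write_any(df, path, format)
  invisible(path)
}

#' @export
write_results.ensemble_result <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  write_any(as.data.frame(x), path, format)
  invisible(path)
}

#' @export
write_results.saturation_fit <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  payload <- list(a = x$a, b = x$b, c = x$c, residual = x$residual,
                  m_star = x$m_star, flag = x$flag, metric = x$metric)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
  } else {
    payload$m_star <- payload$m_star %||% NA
    write_any(as.data.frame(payload), path, "csv")
  }
  invisible(path)
}

#' @export
write_results.cumulative_curve <- function(x, path, format = NULL) {
  format <- resolved_format(path, format)
  df <- data.frame(size = x$sizes, value = x$values,
                   metric = x$metric, variant = x$variant)
  write_any(df, path, format)
  invisible(path)
}

#' @export
write_results.member_matrix <- function(x, path, format = NULL) {
  # wide CSV (id + one column per member) plus a JSON sidecar with the
  # training ranges and retention mask -- the unit of caching between
  # pipeline stages.
  df <- data.frame(id = x$ids, x$values, check.names = FALSE)
  names(df) <- c("id", paste0("member_", seq_len(ncol(x$values))))
  write_any(df, path, "csv")
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(
    list(y = x$y, mask = x$mask, ymin = x$ymin, ymax = x$ymax,
         n_fits = attr(x, "n_fits") %||% NA),
    sidecar, digits = I(17), matrix = "rowmajor", na = "null"
  )
  invisible(path)
}

#' @export
write_results.rank_sum_table <- function(x, path, format = NULL) {
  grid <- rank_sum_grid(x)
  df <- if (is.matrix(grid)) {
    cbind(data.frame(technique = rownames(grid)), as.data.frame(grid))
  } else {
    data.frame(combination = names(grid), rank_sum = as.numeric(grid))
  }
  write_any(df, path, "csv")
  invisible(path)
}

resolved_format <- function(path, format) {
  if (is.null(format)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  } else {
    match.arg(format, c("csv", "json"))
  }
}

write_any <- function(df, path, format) {
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(df, path, dataframe = "rows", digits = I(17),
                           na = "null")
    } else {
      # format() with 17 significant digits keeps the CSV round-trippable
      num <- vapply(df, is.double, TRUE)
      df[num] <- lapply(df[num], function(col) {
        sprintf("%.17g", col)
      })
      write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("failed to write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
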