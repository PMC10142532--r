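#' Construct a feature matrix
#'
#' A numeric matrix with one row per compound plus the featurization kind.
#' Count kinds (`substructure_counts`, `circular_counts`) are scaled per
#' sample to unit Euclidean norm before model fitting; continuous kinds
#' (`physchem`, `learned`) are standardized column-wise on the training
#' partition.
#'
#' @param values numeric matrix, no missing values.
#' @param kind one of `"substructure_counts"`, `"circular_counts"`,
#'   `"physchem"`, `"learned"`.
#' @param feature_names optional character vector of column names.
#' @return A `feature_matrix` (a classed numeric matrix).
#' @export
feature_matrix <- function(values,
                           kind = c("substructure_counts", "circular_counts",
                                    "physchem", "learned"),
                           feature_names = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stopf("feature matrix contains non-finite values")
  if (is_count_kind(kind) && any(values < 0)) {
    stopf("%s features must be non-negative", kind)
  }
  if (!is.null(feature_names)) {
    if (length(feature_names) != ncol(values)) {
      stopf("feature_names length %d != %d columns",
            length(feature_names), ncol(values))
    }
    colnames(values) <- feature_names
  }
  structure(values, kind = kind, class = c("feature_matrix", class(values)))
}

feature_kind <- function(fm) attr(fm, "kind") %||% "learned"

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d, kind = %s\n",
              nrow(x), ncol(x), feature_kind(x)))
  invisible(x)
}

# subsetting keeps the kind whenever the result is still a matrix
#' @export
`[.feature_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) {
    structure(out, kind = attr(x, "kind"),
              class = c("feature_matrix", "matrix", "array"))
  } else {
    out
  }
}

#' Substructure-key count fingerprint (MACCS keys)
#'
#' Counts the occurrences of the public MACCS key substructure patterns
#' (as shipped with the installed chemistry toolkit) for every compound;
#' multiple occurrences of a key are summed rather than collapsed to a
#' bit.  Keys without a SMARTS definition in the toolkit's pattern set
#' are omitted; the realized key set is recorded in the column names.
#'
#' @param smiles character vector of SMILES strings.
#' @return A [feature_matrix()] of kind `substructure_counts` with one
#'   column per available MACCS key (named `maccs_<key>`).
#' @export
maccs_counts <- function(smiles) {
  pat <- maccs_patterns()
  counts <- smarts_count_matrix(smiles, pat$smarts)
  feature_matrix(counts, kind = "substructure_counts",
                 feature_names = paste0("maccs_", pat$key))
}

#' Physicochemical descriptor vector
#'
#' Computes the full set of molecular property descriptors available from
#' the chemistry toolkit (molecular weight, logP, topological polar
#' surface area, molar refractivity, hydrogen-bond donor/acceptor counts,
#' ...) augmented with graph-derived counts (heavy atoms, rings,
#' rotatable bonds, element counts).  The descriptor set is
#' toolkit-version dependent; the realized descriptor names are recorded
#' in the column names rather than asserting a fixed length.  Extreme
#' values are deliberately not clipped here: outlier handling lives on
#' the prediction side (see [filter_outlier_predictions()]).
#'
#' @param smiles character vector of SMILES strings.
#' @return A [feature_matrix()] of kind `physchem`.  Compounds for which
#'   a descriptor evaluates non-finite are flagged via the
#'   `"flagged_compounds"` attribute and the value replaced by 0.
#' @export
physchem_descriptors <- function(smiles) {
  can <- canonical_smiles(smiles)
  input <- paste0(paste0(can, collapse = "\n"), "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, function(mol) mol)
  props <- ChemmineOB::prop_OB(mols)
  numeric_cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  base <- as.matrix(props[, numeric_cols, drop = FALSE])
  graphs <- mol_graphs(smiles)
  graph_desc <- t(vapply(graphs, graph_descriptors, numeric(8)))
  rot <- smarts_count_matrix(
    smiles, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  )[, 1] / 2  # each rotatable bond matches twice (both directions)
  arom <- smarts_count_matrix(smiles, "a")[, 1]
  values <- cbind(base, graph_desc, n_rotatable = rot, n_aromatic_atoms = arom)
  flagged <- which(apply(values, 1L, function(r) any(!is.finite(r))))
  values[!is.finite(values)] <- 0
  out <- feature_matrix(values, kind = "physchem",
                        feature_names = colnames(values))
  attr(out, "flagged_compounds") <- flagged
  out
}

# counts derived from the explicit-H molecular graph
graph_descriptors <- function(g) {
  heavy <- g$elements != "H"
  n_heavy <- sum(heavy)
  hb <- g$bonds[g$elements[g$bonds$a] != "H" & g$elements[g$bonds$b] != "H", ,
                drop = FALSE]
  c(heavy_atoms = n_heavy,
    n_bonds = nrow(hb),
    n_rings = nrow(hb) - n_heavy + n_components(hb, n_heavy, which(heavy)),
    n_C = sum(g$elements == "C"),
    n_N = sum(g$elements == "N"),
    n_O = sum(g$elements == "O"),
    n_halogen = sum(g$elements %in% c("F", "Cl", "Br", "I")),
    total_charge = sum(g$charges))
}

n_components <- function(bonds, n_heavy, heavy_idx) {
  if (n_heavy == 0L) return(0L)
  comp <- seq_len(max(heavy_idx))
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (r in seq_len(nrow(bonds))) {
    ra <- find(bonds$a[r]); rb <- find(bonds$b[r])
    if (ra != rb) comp[ra] <- rb
  }
  length(unique(vapply(heavy_idx, find, 0L)))
}

#' Fit a feature scaler on a training partition
#'
#' Count featurizations get per-sample Euclidean normalization (a
#' stateless transform, so the fitted state carries no column
#' statistics); continuous featurizations get column-wise
#' standardization with the training partition's mean and population
#' standard deviation.  Fitting uses the training rows only, so test
#' rows can never leak into the state.
#'
#' @param train a [feature_matrix()] of training rows (>= 2).
#' @return A `scaler_state` with `kind` `"per_sample_norm"` or
#'   `"standardize"`.  Zero-variance columns under standardization have
#'   their deviation stored as 1 and are flagged in `zero_var_columns`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train) < 2L) stopf("need at least 2 training rows to fit a scaler")
  kind <- feature_kind(train)
  if (is_count_kind(kind)) {
    state <- list(kind = "per_sample_norm", p = ncol(train),
                  feature_kind = kind)
  } else {
    mu <- colMeans(train)
    sdev <- sqrt(colMeans(sweep(unclass(train), 2L, mu)^2))
    zero_var <- which(sdev == 0)
    sdev[zero_var] <- 1
    state <- list(kind = "standardize", p = ncol(train), feature_kind = kind,
                  mean = as.numeric(mu), sd = as.numeric(sdev),
                  zero_var_columns = as.integer(zero_var))
  }
  structure(state, class = "scaler_state")
}

#' Apply a fitted scaler
#'
#' @param features a [feature_matrix()] with the same column count and
#'   kind the scaler was fitted on.
#' @param state a `scaler_state` from [fit_scaler()].
#' @return The scaled `feature_matrix`.  Per-sample normalization divides
#'   each row by its Euclidean norm (zero rows pass through unchanged),
#'   which places entries of non-negative count rows in `[0, 1]`;
#'   standardization applies `(x - train mean) / train sd` per column.
#' @export
apply_scaler <- function(features, state) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(state, "scaler_state"))
  if (ncol(features) != state$p) {
    stopf("scaler fitted on %d columns, features have %d",
          state$p, ncol(features))
  }
  if (feature_kind(features) != state$feature_kind) {
    stopf("scaler fitted on kind '%s', features are '%s'",
          state$feature_kind, feature_kind(features))
  }
  x <- unclass(features)
  out <- if (state$kind == "per_sample_norm") {
    norms <- sqrt(rowSums(x^2))
    norms[norms == 0] <- 1
    x / norms
  } else {
    sweep(sweep(x, 2L, state$mean), 2L, state$sd, `/`)
  }
  structure(out, kind = attr(features, "kind"),
            class = c("feature_matrix", class(unclass(out))))
}
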