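# Hashed circular-substructure count fingerprint (extended-connectivity
# style).  Atom environments of growing radius are assigned integer
# identifiers by iterative neighborhood hashing on the heavy-atom graph;
# each (atom, radius) environment that covers at least one new bond emits
# its identifier, and identifiers are folded into a fixed number of bins
# by modulus, accumulating counts.  Input SMILES are canonicalized first,
# and all neighbor information is sorted before hashing, so the vectors
# are invariant to atom ordering in the input SMILES.

HASH_P <- 2147483647  # 2^31 - 1; products with multiplier stay exact in doubles

hash_ints <- function(ints) {
  h <- 5381
  for (v in ints) h <- (h * 131 + v) %% HASH_P
  h
}

hash_string <- function(s) hash_ints(utf8ToInt(s))

#' Enumerate circular atom environments (unhashed)
#'
#' Lists, for every compound, the atom-centered environments of radius 0
#' up to `radius` together with their integer identifiers, before any
#' folding into bins.  An environment is emitted only while it still
#' grows (covers at least one bond not covered at the previous radius),
#' so terminal atoms in small molecules stop early.  This is the
#' enumeration that [morgan_counts()] folds; the row sum of a
#' fingerprint equals the number of environments listed here.
#'
#' @param smiles character vector of SMILES strings.
#' @param radius maximum neighborhood radius (bonds), default 3.
#' @return A list of data.frames (one per compound) with columns
#'   `atom`, `radius`, `id`.
#' @export
morgan_environments <- function(smiles, radius = 3L) {
  graphs <- mol_graphs(smiles)
  lapply(graphs, enumerate_environments, radius = as.integer(radius))
}

enumerate_environments <- function(g, radius) {
  heavy <- which(g$elements != "H")
  n <- length(heavy)
  if (n == 0L) {
    return(data.frame(atom = integer(0), radius = integer(0), id = numeric(0)))
  }
  pos <- integer(length(g$elements))  # original index -> heavy index
  pos[heavy] <- seq_len(n)

  # split bonds into heavy-heavy (the fingerprint graph) and X-H
  a_h <- g$elements[g$bonds$a] == "H"
  b_h <- g$elements[g$bonds$b] == "H"
  hb <- g$bonds[!a_h & !b_h, , drop = FALSE]
  n_hyd <- integer(n)
  h_rows <- which(xor(a_h, b_h))
  for (r in h_rows) {
    heavy_end <- if (a_h[r]) g$bonds$b[r] else g$bonds$a[r]
    if (g$elements[heavy_end] != "H") {
      n_hyd[pos[heavy_end]] <- n_hyd[pos[heavy_end]] + 1L
    }
  }

  nb <- vector("list", n)     # per heavy atom: matrix of (nbr, order, bond)
  for (r in seq_len(nrow(hb))) {
    ia <- pos[hb$a[r]]; ib <- pos[hb$b[r]]; o <- hb$order[r]
    nb[[ia]] <- rbind(nb[[ia]], c(ib, o, r))
    nb[[ib]] <- rbind(nb[[ib]], c(ia, o, r))
  }
  degree <- vapply(nb, function(m) if (is.null(m)) 0L else nrow(m), 0L)
  valence <- vapply(seq_len(n), function(i) {
    (if (is.null(nb[[i]])) 0L else sum(nb[[i]][, 2L])) + n_hyd[i]
  }, 0L)
  in_ring <- ring_atoms(nb, n, nrow(hb))

  ids <- vapply(seq_len(n), function(i) {
    hash_string(paste(g$elements[heavy[i]], degree[i], n_hyd[i],
                      g$charges[heavy[i]], valence[i], in_ring[i],
                      sep = "|"))
  }, 0)

  bond_sets <- rep(list(integer(0)), n)
  out_atom <- seq_len(n)
  out_radius <- rep(0L, n)
  out_id <- ids

  for (r in seq_len(radius)) {
    new_ids <- ids
    new_sets <- bond_sets
    grew <- logical(n)
    for (i in seq_len(n)) {
      m <- nb[[i]]
      if (is.null(m)) next
      ord <- order(m[, 2L], ids[m[, 1L]])
      msg <- c(r, ids[i])
      for (jj in ord) msg <- c(msg, m[jj, 2L], ids[m[jj, 1L]])
      new_ids[i] <- hash_ints(msg)
      covered <- sort(unique(c(bond_sets[[i]], m[, 3L],
                               unlist(bond_sets[m[, 1L]]))))
      grew[i] <- length(covered) > length(bond_sets[[i]])
      new_sets[[i]] <- covered
    }
    ids <- new_ids
    bond_sets <- new_sets
    if (!any(grew)) break
    out_atom <- c(out_atom, which(grew))
    out_radius <- c(out_radius, rep(r, sum(grew)))
    out_id <- c(out_id, ids[grew])
  }
  data.frame(atom = heavy[out_atom], radius = out_radius, id = out_id)
}

# atoms incident to at least one cycle edge (non-bridge), via a simple
# DFS lowpoint bridge search on the heavy-atom graph
ring_atoms <- function(nb, n, n_bonds) {
  if (n_bonds == 0L) return(rep(FALSE, n))
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridge <- logical(n_bonds)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(u = root, parent_edge = 0L, next_i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      m <- nb[[top$u]]
      if (!is.null(m) && top$next_i <= nrow(m)) {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        v <- m[top$next_i, 1L]; e <- m[top$next_i, 3L]
        if (e == top$parent_edge) next
        if (disc[v] == 0L) {
          timer <- timer + 1L; disc[v] <- low[v] <- timer
          stack[[length(stack) + 1L]] <- list(u = v, parent_edge = e,
                                              next_i = 1L)
        } else {
          low[top$u] <- min(low[top$u], disc[v])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          parent <- stack[[length(stack)]]$u
          low[parent] <- min(low[parent], low[top$u])
          if (low[top$u] > disc[parent]) bridge[top$parent_edge] <- TRUE
        }
      }
    }
  }
  in_ring <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- nb[[i]]
    if (!is.null(m) && any(!bridge[m[, 3L]])) in_ring[i] <- TRUE
  }
  in_ring
}

#' Hashed circular count fingerprint
#'
#' Folds the environment identifiers from [morgan_environments()] into
#' `n_bins` bins by modulus and counts occurrences, yielding integer
#' count vectors of fixed length (the count analogue of a hashed
#' extended-connectivity fingerprint; defaults follow common practice:
#' radius 3, 2048 bins).
#'
#' @inheritParams morgan_environments
#' @param n_bins number of hash bins (vector length), default 2048.
#' @return A [feature_matrix()] of kind `circular_counts`, dimensions
#'   `length(smiles) x n_bins`.
#' @export
morgan_counts <- function(smiles, radius = 3L, n_bins = 2048L) {
  envs <- morgan_environments(smiles, radius = radius)
  n_bins <- as.integer(n_bins)
  values <- t(vapply(envs, function(e) {
    tabulate((e$id %% n_bins) + 1L, nbins = n_bins)
  }, integer(n_bins)))
  feature_matrix(values, kind = "circular_counts",
                 feature_names = paste0("mfc_", seq_len(n_bins)))
}
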