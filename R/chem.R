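# Thin layer over the OpenBabel bindings (ChemmineOB): SMILES
# canonicalization, molecular-graph extraction from molfiles, and SMARTS
# match counting.  Everything downstream (dedup keys, featurizers) goes
# through these helpers so the toolkit is touched in exactly one place.

# Canonical SMILES for a character vector, preserving order.
# Unparsable entries raise an error naming the offending indices.
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  bad <- !nzchar(smiles) | is.na(smiles)
  if (any(bad)) {
    stopf("empty SMILES at index %s", paste(which(bad), collapse = ", "))
  }
  input <- paste0(smiles, " mol", seq_along(smiles), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(input, "\n"),
    options = data.frame(names = character(0), args = character(0))
  ))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, "", 1L)
  title <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
  idx <- as.integer(sub("^mol", "", title))
  result <- rep(NA_character_, length(smiles))
  result[idx] <- can
  if (anyNA(result)) {
    stopf("unparsable SMILES at index %s",
          paste(which(is.na(result)), collapse = ", "))
  }
  result
}

# Parse the molecules of a SMILES vector into simple graph structures:
# per molecule a list with `elements`, `charges` (formal), and a bond
# data.frame (a, b, order), hydrogens explicit.  Used by the circular
# fingerprint and the graph-derived descriptors.
mol_graphs <- function(smiles) {
  can <- canonical_smiles(smiles)
  input <- paste0(paste0(can, " m", seq_along(can), collapse = "\n"), "\n")
  sdf <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", input,
    options = data.frame(names = "h", args = "")
  ))
  blocks <- strsplit(sdf, "\\${4}\n?")[[1]]
  blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b), TRUE)]
  if (length(blocks) != length(smiles)) {
    stopf("molfile conversion returned %d molecules for %d SMILES",
          length(blocks), length(smiles))
  }
  lapply(blocks, parse_molfile_block)
}

parse_molfile_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts_i <- grep("V2000", lines)[1]
  n_atoms <- as.integer(substr(lines[counts_i], 1L, 3L))
  n_bonds <- as.integer(substr(lines[counts_i], 4L, 6L))
  atom_lines <- lines[seq.int(counts_i + 1L, length.out = n_atoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  bonds <- if (n_bonds > 0L) {
    bl <- lines[seq.int(counts_i + n_atoms + 1L, length.out = n_bonds)]
    data.frame(
      a = as.integer(substr(bl, 1L, 3L)),
      b = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- fields[1L]
    for (j in seq_len(k)) {
      charges[fields[2L * j]] <- fields[2L * j + 1L]
    }
  }
  list(elements = elements, charges = charges, bonds = bonds)
}

# Count SMARTS matches (non-unique, i.e. every mapping counted) for each
# molecule x pattern.  Returns an integer matrix n x length(patterns).
smarts_count_matrix <- function(smiles, patterns) {
  can <- canonical_smiles(smiles)
  input <- paste0(paste0(can, collapse = "\n"), "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, function(mol) mol)
  out <- matrix(0L, nrow = length(smiles), ncol = length(patterns))
  for (j in seq_along(patterns)) {
    out[, j] <- as.integer(
      ChemmineOB::smartsSearch_OB(mols, patterns[j], uniqueMatches = FALSE)
    )
  }
  out
}

# Locate and parse the MACCS key SMARTS definitions shipped with the
# installed OpenBabel data (entries of the public 166-key set; keys with
# no SMARTS equivalent are listed as '?' and skipped).  Cached per session.
maccs_env <- new.env(parent = emptyenv())

maccs_patterns <- function() {
  if (!is.null(maccs_env$patterns)) return(maccs_env$patterns)
  path <- system.file("openbabel_data", "MACCS.txt", package = "ChemmineOB")
  if (!nzchar(path) || !file.exists(path)) {
    stopf("MACCS key definitions not found in the installed ChemmineOB data")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- grep("^\\s*[0-9]+:\\(", lines, value = TRUE)
  m <- regmatches(lines, regexec("^\\s*([0-9]+):\\('(.*)',([0-9]+)\\)", lines))
  keep <- vapply(m, length, 0L) == 4L
  m <- m[keep]
  key <- vapply(m, `[`, "", 2L)
  smarts <- vapply(m, `[`, "", 3L)
  ok <- smarts != "?" & nzchar(smarts)
  pat <- data.frame(key = as.integer(key[ok]), smarts = smarts[ok],
                    stringsAsFactors = FALSE)
  # keep only patterns OpenBabel can actually compile
  probe <- ChemmineOB::forEachMol("SMILES", "C\n", function(mol) mol)
  compiles <- vapply(pat$smarts, function(s) {
    !inherits(tryCatch(
      ChemmineOB::smartsSearch_OB(probe, s, uniqueMatches = FALSE),
      error = function(e) e
    ), "error")
  }, TRUE)
  pat <- pat[compiles, , drop = FALSE]
  maccs_env$patterns <- pat
  pat
}
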