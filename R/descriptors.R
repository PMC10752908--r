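# Descriptor blocks: the nine fingerprint families, as fixed-width matrices.
#
# MACCS (166 structural keys, via OpenBabel) and RDK5 (2048-bit hashed path
# fingerprint, max path length 5, computed natively over the molecular graph)
# are produced in-process. The remaining seven PaDEL-Descriptor families
# (AP2D/AP2DC, KR/KRC, Pubchem, FP4/FP4C) enter via validated import of
# PaDEL-format CSV matrices: re-deriving their SMARTS libraries is out of
# scope and import preserves bit-exact compatibility with the reference tool.

.FP_REGISTRY <- tibble::tribble(
  ~name,      ~width, ~value_kind, ~provenance,
  "AP2D",     780L,   "binary",    "imported",
  "AP2DC",    780L,   "count",     "imported",
  "KR",       4860L,  "binary",    "imported",
  "KRC",      4860L,  "count",     "imported",
  "MACCS",    166L,   "binary",    "native",
  "Pubchem",  881L,   "binary",    "imported",
  "FP4",      307L,   "binary",    "imported",
  "FP4C",     307L,   "count",     "imported",
  "RDK5",     2048L,  "binary",    "native"
)

#' Fingerprint family registry
#'
#' The nine supported fingerprint families with their fixed widths, value
#' semantics (binary presence bits vs substructure counts) and provenance
#' (computed natively or imported from PaDEL-format CSV).
#'
#' @return A tibble with columns `name`, `width`, `value_kind`, `provenance`.
#' @export
fp_registry <- function() .FP_REGISTRY

#' Look up one registry entry
#'
#' @param name One of the nine family names (e.g. `"MACCS"`, `"Pubchem"`).
#' @return A one-row tibble from [fp_registry()].
#' @export
registry_entry <- function(name) {
  hit <- .FP_REGISTRY[.FP_REGISTRY$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) {
    abort(sprintf("unknown fingerprint family '%s' (registry error)", name))
  }
  hit
}

new_fp_block <- function(name, matrix, row_ids) {
  entry <- registry_entry(name)
  if (ncol(matrix) != entry$width) {
    abort(sprintf("fingerprint block '%s': expected %d columns, found %d",
                  name, entry$width, ncol(matrix)))
  }
  rownames(matrix) <- row_ids
  structure(list(name = name, matrix = matrix,
                 value_kind = entry$value_kind, row_ids = row_ids),
            class = "fp_block")
}

#' @method print fp_block
#' @export
print.fp_block <- function(x, ...) {
  cat(sprintf("<fp_block> %s: %d compounds x %d features (%s)\n",
              x$name, nrow(x$matrix), ncol(x$matrix), x$value_kind))
  invisible(x)
}

#' @export
dim.fp_block <- function(x) dim(x$matrix)

# ---- native MACCS ----------------------------------------------------------

maccs_bits <- function(smiles) {
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), "MACCS")
  # OpenBabel stores the 166 keys 1-indexed in a 256-bit container; the first
  # 166 positions are the standard key numbers.
  as.integer(fp[1:166])
}

# ---- native hashed path fingerprint (RDK5 family) --------------------------

# Parse a molecule into an atom/bond graph via an SDF conversion.
mol_graph <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(integer(), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

# Enumerate every simple path of 1..max_len bonds; each path contributes one
# canonical invariant string (the lexicographically smaller of the forward and
# reverse element/bond-order sequences), and the set of unique strings is
# hashed into `nbits` buckets.
hashed_path_bits <- function(graph, max_len = 5L, nbits = 2048L) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(integer(0))
  adj <- vector("list", length(graph$elements))
  for (i in seq_len(nb)) {
    a <- graph$bonds[i, 1]; b <- graph$bonds[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  paths <- character(0)
  walk <- function(atom_seq, bond_seq) {
    last <- atom_seq[length(atom_seq)]
    if (length(bond_seq) > 0L) {
      fwd <- path_string(graph, atom_seq, bond_seq)
      rev_ <- path_string(graph, rev(atom_seq), rev(bond_seq))
      paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    }
    if (length(bond_seq) == max_len) return(invisible())
    nbrs <- adj[[last]]
    if (is.null(nbrs)) return(invisible())
    for (r in seq_len(nrow(nbrs))) {
      nxt <- nbrs[r, 1]
      if (nxt %in% atom_seq) next  # simple paths only
      walk(c(atom_seq, nxt), c(bond_seq, nbrs[r, 2]))
    }
    invisible()
  }
  for (start in seq_along(graph$elements)) walk(start, integer(0))
  bits <- vapply(unique(paths), fnv1a_bucket, integer(1), buckets = nbits)
  sort(unique(bits))
}

path_string <- function(graph, atom_seq, bond_seq) {
  out <- graph$elements[atom_seq[1]]
  for (i in seq_along(bond_seq)) {
    out <- paste0(out, graph$bonds[bond_seq[i], 3], graph$elements[atom_seq[i + 1]])
  }
  out
}

rdk5_bits <- function(sdf_mol) {
  hashed_path_bits(mol_graph(sdf_mol), max_len = 5L, nbits = 2048L)
}

# ---- block-level operations ------------------------------------------------

#' Compute a native fingerprint block
#'
#' Computes the MACCS (166 structural keys) or RDK5-family (2048-bit hashed
#' path fingerprint, maximum path length 5 bonds) block for a curated
#' compound table. Both are deterministic functions of the canonical SMILES.
#'
#' @param data Curated tibble with `id` and `smiles_canonical` columns.
#' @param name `"MACCS"` or `"RDK5"`.
#' @return An `fp_block`.
#' @export
compute_fp <- function(data, name = c("MACCS", "RDK5")) {
  name <- match.arg(name)
  entry <- registry_entry(name)
  if (entry$provenance != "native") {
    abort(sprintf("'%s' is not natively computable; use import_fp_block()", name))
  }
  n <- nrow(data)
  mat <- matrix(0L, nrow = n, ncol = entry$width)
  colnames(mat) <- paste0(name, seq_len(entry$width))
  if (n > 0L) {
    if (name == "MACCS") {
      for (i in seq_len(n)) {
        mat[i, ] <- maccs_bits(data$smiles_canonical[i])
      }
    } else {
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        stats::setNames(data$smiles_canonical, data$id)))
      for (i in seq_len(n)) {
        on_bits <- rdk5_bits(sdf[[i]])
        if (length(on_bits)) mat[i, on_bits] <- 1L
      }
    }
  }
  new_fp_block(name, mat, data$id)
}

#' Import a precomputed fingerprint block
#'
#' Reads a PaDEL-Descriptor-format CSV (first column `Name` holding compound
#' ids, remaining columns one feature each), validates it against the family
#' registry (exact width; binary blocks must contain only 0/1; count blocks
#' non-negative integers) and reorders rows to match the compound table.
#'
#' @param path CSV file path.
#' @param name Registry family name the file claims to contain.
#' @param data Curated tibble whose `id` order the block must follow.
#' @return An `fp_block` aligned with `data`.
#' @export
import_fp_block <- function(path, name, data) {
  entry <- registry_entry(name)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_double(),
                           Name = readr::col_character()))
  if (!"Name" %in% names(raw)) names(raw)[1] <- "Name"
  raw$Name <- as.character(raw$Name)
  found <- ncol(raw) - 1L
  if (found != entry$width) {
    abort(sprintf(
      "schema error for '%s': expected %d feature columns, found %d",
      name, entry$width, found))
  }
  missing <- setdiff(data$id, raw$Name)
  if (length(missing)) {
    abort(sprintf("alignment error: %d compound id(s) missing from %s (e.g. %s)",
                  length(missing), path, missing[1]))
  }
  mat <- as.matrix(raw[match(data$id, raw$Name), -1, drop = FALSE])
  if (anyNA(mat)) abort(sprintf("non-numeric values in fingerprint file %s", path))
  if (entry$value_kind == "binary") {
    if (!all(mat %in% c(0, 1))) {
      abort(sprintf("value error: binary block '%s' contains values outside {0,1}",
                    name))
    }
  } else {
    if (any(mat < 0) || any(mat != floor(mat))) {
      abort(sprintf("value error: count block '%s' must hold non-negative integers",
                    name))
    }
  }
  storage.mode(mat) <- "integer"
  new_fp_block(name, mat, data$id)
}

#' Write a fingerprint block as PaDEL-format CSV
#'
#' @param block An `fp_block`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fp_block <- function(block, path) {
  df <- tibble::as_tibble(block$matrix)
  df <- dplyr::bind_cols(tibble(Name = block$row_ids), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Descriptor families available for a run
#'
#' The natively computable families plus every family with a configured
#' import file; the stacking layer consumes exactly this list.
#'
#' @param import_paths Named list/vector mapping family names to CSV paths
#'   (may be `NULL`).
#' @return Character vector of family names, in registry order.
#' @export
available_descriptors <- function(import_paths = NULL) {
  imported <- names(import_paths %||% character())
  for (nm in imported) registry_entry(nm)
  avail <- union(.FP_REGISTRY$name[.FP_REGISTRY$provenance == "native"], imported)
  .FP_REGISTRY$name[.FP_REGISTRY$name %in% avail]
}

#' Build all requested fingerprint blocks
#'
#' @param data Curated tibble (`id`, `smiles_canonical`).
#' @param names Families to build.
#' @param import_paths Named list of PaDEL CSV paths for imported families.
#' @return Named list of `fp_block`s, in the order of `names`.
#' @export
compute_fp_blocks <- function(data, names, import_paths = NULL) {
  out <- lapply(names, function(nm) {
    entry <- registry_entry(nm)
    if (entry$provenance == "native") {
      compute_fp(data, nm)
    } else {
      path <- import_paths[[nm]]
      if (is.null(path)) {
        abort(sprintf("no import file configured for descriptor '%s'", nm))
      }
      import_fp_block(path, nm, data)
    }
  })
  stats::setNames(out, names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
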