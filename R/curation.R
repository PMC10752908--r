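# Curation: raw SMILES/IC50 tables -> standardized, labeled, split datasets.
#
# The pipeline mirrors standard ChEMBL-style bioactivity curation: resolve
# columns and units, strip salts and keep the largest organic fragment,
# canonicalize, collapse duplicate structures to a median IC50, label by
# potency thresholds, and draw a stratified train/test split.

#' Activity labeling thresholds
#'
#' Compounds with IC50 at or below `active_max_nM` are labeled active, at or
#' above `inactive_min_nM` inactive; values strictly between are intermediate
#' and are conventionally excluded from modeling.
#'
#' @param active_max_nM Upper IC50 bound (nM) for the active class.
#' @param inactive_min_nM Lower IC50 bound (nM) for the inactive class.
#' @return A `label_thresholds` object.
#' @examples
#' label_thresholds()
#' label_thresholds(500, 5000)
#' @export
label_thresholds <- function(active_max_nM = 1000, inactive_min_nM = 10000) {
  stopifnot_scalar_number(active_max_nM, "active_max_nM")
  stopifnot_scalar_number(inactive_min_nM, "inactive_min_nM")
  if (active_max_nM <= 0 || inactive_min_nM <= 0) {
    abort("thresholds must be positive")
  }
  if (active_max_nM >= inactive_min_nM) {
    abort("`active_max_nM` must be strictly below `inactive_min_nM`")
  }
  structure(list(active_max_nM = active_max_nM,
                 inactive_min_nM = inactive_min_nM),
            class = "label_thresholds")
}

#' Read a compound bioactivity table
#'
#' Reads a CSV or tab-separated compound table and normalizes it to the
#' three-column form the rest of the pipeline consumes: `id`, `smiles_raw`,
#' `ic50_nM`. Two column dialects are understood: `generic_csv` (columns
#' `id`, `smiles`, `ic50_nM`, or `ic50` plus a `unit`/`units` column) and
#' `chembl_export` (a ChEMBL bioactivity export with `Molecule ChEMBL ID`,
#' `Smiles`, `Standard Value`, `Standard Units`). Units are converted to nM
#' where unambiguous (pM, nM, uM/µM, mM, M); rows with other units are dropped
#' with a warning or rejected, per `on_bad_units`. Unparseable IC50 values
#' become missing (the row is kept and later labeled `unlabeled`).
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"generic_csv"` or `"chembl_export"`.
#' @param on_bad_units `"drop"` (default) or `"error"` for rows whose unit
#'   cannot be converted to nM.
#' @return A tibble with columns `id`, `smiles_raw`, `ic50_nM`.
#' @export
read_compound_table <- function(path,
                                dialect = c("generic_csv", "chembl_export"),
                                on_bad_units = c("drop", "error")) {
  dialect <- match.arg(dialect)
  on_bad_units <- match.arg(on_bad_units)
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) abort("empty input file")
  delim <- if (grepl("\t", first)) "\t" else if (grepl(";", first) && !grepl(",", first)) ";" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) abort("empty input file")
  cols <- if (dialect == "chembl_export") {
    list(id = c("Molecule ChEMBL ID", "molecule_chembl_id"),
         smiles = c("Smiles", "canonical_smiles"),
         value = c("Standard Value", "standard_value"),
         unit = c("Standard Units", "standard_units"))
  } else {
    list(id = c("id", "compound_id", "name", "Name"),
         smiles = c("smiles", "SMILES", "smiles_raw"),
         value = c("ic50_nM", "ic50_nm", "ic50", "IC50"),
         unit = c("unit", "units"))
  }
  pick <- function(cands) {
    hit <- cands[cands %in% names(raw)]
    if (length(hit)) hit[[1]] else NA_character_
  }
  id_col <- pick(cols$id); smi_col <- pick(cols$smiles); val_col <- pick(cols$value)
  if (is.na(smi_col)) abort("no SMILES column found (configuration error)")
  if (is.na(val_col)) abort("no IC50 column found (configuration error)")
  if (is.na(id_col)) {
    raw$.id <- sprintf("cmpd_%d", seq_len(nrow(raw)))
    id_col <- ".id"
  }
  unit_col <- pick(cols$unit)
  value <- suppressWarnings(as.numeric(raw[[val_col]]))
  unit <- if (!is.na(unit_col)) raw[[unit_col]] else {
    # generic dialect with an ic50_nM column is already in nM
    if (tolower(val_col) %in% c("ic50_nm")) rep("nM", nrow(raw)) else rep("nM", nrow(raw))
  }
  unit_clean <- tolower(trimws(ifelse(is.na(unit), "nM", unit)))
  factor_map <- c("pm" = 1e-3, "nm" = 1, "um" = 1e3, "µm" = 1e3,
                  "μm" = 1e3, "mm" = 1e6, "m" = 1e9)
  fac <- unname(factor_map[unit_clean])
  bad <- !is.na(value) & is.na(fac)
  if (any(bad)) {
    if (on_bad_units == "error") {
      abort(sprintf("unconvertible IC50 unit(s): %s",
                    paste(unique(unit_clean[bad]), collapse = ", ")))
    }
    warn(sprintf("dropping %d row(s) with unconvertible IC50 units (%s)",
                 sum(bad), paste(unique(unit_clean[bad]), collapse = ", ")))
  }
  out <- tibble(id = as.character(raw[[id_col]]),
                smiles_raw = as.character(raw[[smi_col]]),
                ic50_nM = value * ifelse(is.na(fac), NA_real_, fac))
  out <- out[!bad, , drop = FALSE]
  if (any(!is.na(out$ic50_nM) & out$ic50_nM <= 0)) {
    abort("IC50 values must be strictly positive")
  }
  out
}

# Split a SMILES into dot-separated components. The dot is the component
# separator in the SMILES grammar and cannot occur inside brackets.
smiles_components <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

# Count heavy atoms and carbons from a SMILES string by tokenizing bracket
# atoms and the organic-subset symbols (sufficient for fragment ranking).
smiles_atom_counts <- function(smiles) {
  body <- gsub("\\[[^]]*\\]", "", smiles)  # each bracket atom -> 1 token
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  organic <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", body)[[1]]
  n_org <- if (organic[1] == -1) 0L else length(organic)
  toks <- if (organic[1] == -1) character() else regmatches(body, gregexpr(
    "Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", body))[[1]]
  n_carbon <- sum(toks %in% c("C", "c")) +
    sum(grepl("\\[[0-9]*[Cc](?![lladoeurfs])", brackets, perl = TRUE))
  heavy <- n_org + length(brackets) -
    sum(grepl("^\\[[0-9]*H[0-9+-]*\\]$", brackets))  # explicit hydrogens
  list(heavy = heavy, carbon = n_carbon)
}

ob_canonical <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

#' Standardize a chemical structure
#'
#' Desalts and canonicalizes one SMILES string: the input is split into
#' covalently disconnected components, each component is canonicalized, and
#' the largest organic (carbon-containing) fragment is retained. The result
#' is the toolkit-canonical SMILES of that fragment, so the operation is
#' idempotent.
#'
#' @param smiles_raw A single SMILES string.
#' @return The canonical, desalted SMILES string.
#' @examples
#' standardize_structure("CCO.Cl")   # -> "CCO"
#' @export
standardize_structure <- function(smiles_raw) {
  if (!is.character(smiles_raw) || length(smiles_raw) != 1L || is.na(smiles_raw)) {
    abort("`smiles_raw` must be a single SMILES string")
  }
  parts <- smiles_components(smiles_raw)
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0L) abort(sprintf("unparseable SMILES: %s", smiles_raw))
  canon <- vapply(parts, ob_canonical, character(1))
  if (any(is.na(canon))) {
    abort(sprintf("unparseable SMILES: %s", smiles_raw),
          class = "qsarstack_parse_error")
  }
  counts <- lapply(canon, smiles_atom_counts)
  has_c <- vapply(counts, function(x) x$carbon > 0, logical(1))
  if (!any(has_c)) {
    abort(sprintf("no organic fragment after desalting: %s", smiles_raw),
          class = "qsarstack_inorganic_error")
  }
  heavy <- vapply(counts, function(x) x$heavy, numeric(1))
  heavy[!has_c] <- -Inf
  unname(canon[[which.max(heavy)]])
}

#' Standardize every structure in a compound table
#'
#' Vectorized [standardize_structure()] over a compound tibble. Rows whose
#' SMILES fail to parse (or contain no organic fragment) are either dropped
#' with a warning or raise an error.
#'
#' @param data Tibble with columns `id`, `smiles_raw` (and typically
#'   `ic50_nM`).
#' @param on_error `"drop"` (default) or `"error"`.
#' @return The input tibble with a `smiles_canonical` column added and
#'   invalid rows removed.
#' @export
standardize_compounds <- function(data, on_error = c("drop", "error")) {
  on_error <- match.arg(on_error)
  res <- purrr::map(data$smiles_raw, function(s) {
    tryCatch(list(ok = TRUE, smiles = standardize_structure(s)),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (any(!ok)) {
    if (on_error == "error") abort(res[[which(!ok)[1]]]$msg)
    warn(sprintf("dropping %d structure(s) that failed standardization",
                 sum(!ok)))
  }
  out <- data[ok, , drop = FALSE]
  out$smiles_canonical <- vapply(res[ok], `[[`, character(1), "smiles")
  out
}

#' Collapse duplicate structures
#'
#' One record is kept per canonical SMILES (first occurrence order, first id
#' retained); the retained IC50 is the median of the duplicates' IC50 values,
#' which is robust to the assay outliers common in public bioactivity data.
#'
#' @param data Tibble with `smiles_canonical` and `ic50_nM` columns.
#' @return Deduplicated tibble.
#' @export
deduplicate_compounds <- function(data) {
  if (nrow(data) == 0L) return(data)
  data |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$smiles_canonical) |>
    dplyr::summarise(
      id = dplyr::first(.data$id),
      smiles_raw = dplyr::first(.data$smiles_raw),
      ic50_nM = if (all(is.na(.data$ic50_nM))) NA_real_ else
        stats::median(.data$ic50_nM, na.rm = TRUE),
      .ord = min(.data$.ord),
      .groups = "drop") |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("id", "smiles_raw", "smiles_canonical", "ic50_nM")
}

#' Assign activity labels from IC50 values
#'
#' Partitions the positive IC50 axis into three intervals: active
#' (`ic50 <= active_max_nM`), inactive (`ic50 >= inactive_min_nM`) and
#' intermediate (strictly between). Missing IC50 values map to `unlabeled`.
#'
#' @param ic50_nM Numeric vector of IC50 values in nM (NA allowed).
#' @param thresholds A [label_thresholds()] object.
#' @return Factor with levels `active`, `inactive`, `intermediate`,
#'   `unlabeled`.
#' @export
assign_label <- function(ic50_nM, thresholds = label_thresholds()) {
  stopifnot(inherits(thresholds, "label_thresholds"))
  if (any(!is.na(ic50_nM) & ic50_nM <= 0)) abort("IC50 values must be > 0")
  lab <- ifelse(is.na(ic50_nM), "unlabeled",
         ifelse(ic50_nM <= thresholds$active_max_nM, "active",
         ifelse(ic50_nM >= thresholds$inactive_min_nM, "inactive",
                "intermediate")))
  factor(lab, levels = c("active", "inactive", "intermediate", "unlabeled"))
}

#' Curate a raw compound table
#'
#' Full curation pipeline: standardize structures, deduplicate by canonical
#' SMILES, assign activity labels. Intermediate and unlabeled records are kept
#' in the returned table (with their labels) so callers can inspect them, but
#' downstream modeling helpers use only active/inactive rows.
#'
#' @param data Tibble from [read_compound_table()] (columns `id`,
#'   `smiles_raw`, `ic50_nM`).
#' @param thresholds A [label_thresholds()] object.
#' @param on_error Passed to [standardize_compounds()].
#' @return Curated tibble with columns `id`, `smiles_raw`, `smiles_canonical`,
#'   `ic50_nM`, `label`.
#' @export
curate_compounds <- function(data, thresholds = label_thresholds(),
                             on_error = c("drop", "error")) {
  data |>
    standardize_compounds(on_error = on_error) |>
    deduplicate_compounds() |>
    dplyr::mutate(label = assign_label(.data$ic50_nM, thresholds))
}

#' Stratified train/test split
#'
#' Within each activity class exactly `floor(train_fraction * class_size)`
#' records are drawn uniformly at random (under `seed`) into the training
#' split; the remainder form the test split. Records that are not
#' active/inactive receive split `"none"`.
#'
#' @param data Curated tibble with a `label` column.
#' @param train_fraction Fraction in (0, 1].
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return The tibble with a `split` column (`train`/`test`/`none`).
#' @export
stratified_split <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("`train_fraction` must lie in (0, 1]")
  }
  lab <- as.character(data$label)
  modeled <- lab %in% c("active", "inactive")
  for (cls in c("active", "inactive")) {
    if (sum(lab == cls) == 0L) {
      abort(sprintf("cannot stratify: class '%s' has no members", cls))
    }
  }
  split <- rep("none", nrow(data))
  withr::with_seed(seed, {
    for (cls in c("active", "inactive")) {
      idx <- which(lab == cls)
      n_train <- floor(train_fraction * length(idx))
      tr <- sample(idx, n_train)
      split[idx] <- "test"
      split[tr] <- "train"
    }
  })
  data$split <- factor(split, levels = c("train", "test", "none"))
  data
}

#' Write / read a curated dataset as CSV
#'
#' Lossless CSV round-trip of a curated (optionally split) compound table.
#'
#' @param data Curated tibble.
#' @param path Output CSV path.
#' @return `write_curated_csv` returns `path` invisibly; `read_curated_csv`
#'   returns the curated tibble.
#' @export
write_curated_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_curated_csv
#' @export
read_curated_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           ic50_nM = readr::col_double(),
                           .default = readr::col_character()))
  if ("label" %in% names(out)) {
    out$label <- factor(out$label,
                        levels = c("active", "inactive", "intermediate", "unlabeled"))
  }
  if ("split" %in% names(out)) {
    out$split <- factor(out$split, levels = c("train", "test", "none"))
  }
  as_tibble(out)
}
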