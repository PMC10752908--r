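# Synthetic fixture generator: labeled SMILES tables with planted
# substructure motifs, plus PaDEL-style fingerprint matrices with
# controllable label correlation. Gives every pipeline stage a recoverable
# ground truth without any external download.

ACTIVE_MOTIFS <- c("FC(F)(F)", "FC(F)", "CN(C)", "CCN(CC)")
NEUTRAL_GROUPS <- c("CC(C)(C)", "C1CC1", "OC(C)", "CCOC", "CC(C)O", "C(=O)C")
TAIL_GROUPS <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
                 "CCCCCCCC", "CCCCCCCCC", "CCCCCCCCCC", "O", "OC", "OCC",
                 "OCCC", "C(C)CC", "CC(C)C", "CCO", "OC(C)C")
SCAFFOLD_TEMPLATES <- c("%sc1ccc(%s)cc1",                 # para benzene
                        "%sc1cccc(%s)c1",                 # meta benzene
                        "%sC1CCC(%s)CC1",                 # cyclohexane
                        "%sc1ccc(-c2ccc(%s)cc2)cc1",      # biphenyl
                        "%sc1ccc(C(=O)%s)cc1")            # aryl ketone
SALT_SUFFIXES <- c(".Cl", ".[Na+]", ".OS(=O)(=O)O")
INVALID_SMILES <- c("C1CC", "xyz123", "C1CCCC", "C1CCCCC", "Q")

#' Specification for a synthetic compound dataset
#'
#' Describes a planted-motif dataset: actives carry fluorinated or
#' tertiary-amine decorations on simple scaffolds, inactives carry neutral
#' groups, so fingerprints capturing the motifs separate the classes.
#' `label_noise` is the fraction of compounds whose IC50 (hence label) is
#' drawn from the opposite class's range, decoupling label from structure.
#' IC50 ranges default to U(10, 900) nM for actives and U(12000, 90000) nM
#' for inactives, safely inside the default labeling thresholds.
#'
#' @param n_active,n_inactive Compounds per structural class.
#' @param label_noise Label-flip rate in \[0, 0.5).
#' @param active_ic50,inactive_ic50 IC50 sampling ranges (nM).
#' @param salt_rate,duplicate_rate,invalid_rate Rates of injected salt
#'   adducts, duplicated structures and unparseable rows, each in \[0, 1).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_active = 300L, n_inactive = 300L,
                           label_noise = 0.1,
                           active_ic50 = c(10, 900),
                           inactive_ic50 = c(12000, 90000),
                           salt_rate = 0, duplicate_rate = 0,
                           invalid_rate = 0, seed = 1L) {
  for (r in list(salt_rate, duplicate_rate, invalid_rate)) {
    if (r < 0 || r >= 1) abort("rates must lie in [0, 1)")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("`label_noise` must lie in [0, 0.5)")
  }
  thr <- label_thresholds()
  if (active_ic50[2] > thr$active_max_nM || inactive_ic50[1] < thr$inactive_min_nM) {
    abort("IC50 ranges must respect the default labeling thresholds")
  }
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 label_noise = label_noise,
                 active_ic50 = active_ic50, inactive_ic50 = inactive_ic50,
                 salt_rate = salt_rate, duplicate_rate = duplicate_rate,
                 invalid_rate = invalid_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

enumerate_class_smiles <- function(groups) {
  combos <- expand.grid(template = SCAFFOLD_TEMPLATES, g = groups,
                        tail = TAIL_GROUPS, stringsAsFactors = FALSE)
  sprintf(combos$template, combos$g, combos$tail)
}

#' Generate a raw labeled compound table
#'
#' Builds `n_active + n_inactive` unique molecules by decorating simple
#' scaffolds (benzene, cyclohexane, biphenyl, aryl ketone) with motif groups
#' (actives) or neutral groups (inactives), draws IC50 values within the
#' class ranges (flipped to the opposite range at rate `label_noise`), and
#' injects salt adducts, duplicate rows and invalid SMILES at the configured
#' rates. The `true_class` column records the intended post-curation label;
#' `motif` records whether the structure carries an active motif.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `id`, `smiles_raw`, `ic50_nM`, `true_class`,
#'   `motif`.
#' @export
gen_labeled_smiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pool_act <- enumerate_class_smiles(ACTIVE_MOTIFS)
  pool_ina <- enumerate_class_smiles(NEUTRAL_GROUPS)
  if (spec$n_active > length(pool_act) || spec$n_inactive > length(pool_ina)) {
    abort(sprintf("at most %d active / %d inactive unique structures available",
                  length(pool_act), length(pool_ina)))
  }
  withr::with_seed(spec$seed, {
    smi <- c(sample(pool_act, spec$n_active),
             sample(pool_ina, spec$n_inactive))
    motif <- rep(c(TRUE, FALSE), c(spec$n_active, spec$n_inactive))
    flip <- stats::runif(length(smi)) < spec$label_noise
    is_active <- xor(motif, flip)
    ic50 <- ifelse(is_active,
                   stats::runif(length(smi), spec$active_ic50[1], spec$active_ic50[2]),
                   stats::runif(length(smi), spec$inactive_ic50[1], spec$inactive_ic50[2]))
    out <- tibble(id = sprintf("syn_%04d", seq_along(smi)),
                  smiles_raw = smi, ic50_nM = ic50,
                  true_class = factor(ifelse(is_active, "active", "inactive"),
                                      levels = c("active", "inactive")),
                  motif = motif)
    out <- out[sample(nrow(out)), , drop = FALSE]
    # salt adducts
    n_salt <- floor(spec$salt_rate * nrow(out))
    if (n_salt > 0) {
      rows <- sample(nrow(out), n_salt)
      out$smiles_raw[rows] <- paste0(out$smiles_raw[rows],
                                     sample(SALT_SUFFIXES, n_salt, replace = TRUE))
    }
    # duplicated structures under fresh ids, IC50 re-drawn in-class
    n_dup <- floor(spec$duplicate_rate * nrow(out))
    if (n_dup > 0) {
      rows <- sample(nrow(out), n_dup)
      dup <- out[rows, , drop = FALSE]
      dup$id <- sprintf("syn_dup_%04d", seq_len(n_dup))
      act <- dup$true_class == "active"
      dup$ic50_nM <- ifelse(act,
                            stats::runif(n_dup, spec$active_ic50[1], spec$active_ic50[2]),
                            stats::runif(n_dup, spec$inactive_ic50[1], spec$inactive_ic50[2]))
      out <- dplyr::bind_rows(out, dup)
    }
    # unparseable rows
    n_bad <- floor(spec$invalid_rate * nrow(out))
    if (n_bad > 0) {
      bad <- tibble(id = sprintf("syn_bad_%04d", seq_len(n_bad)),
                    smiles_raw = sample(INVALID_SMILES, n_bad, replace = TRUE),
                    ic50_nM = stats::runif(n_bad, 10, 90000),
                    true_class = factor(NA, levels = c("active", "inactive")),
                    motif = NA)
      out <- dplyr::bind_rows(out, bad)
    }
    out
  })
}

#' Generate a synthetic fingerprint block
#'
#' Emits a registry-width matrix for one descriptor family in which a
#' configurable fraction of columns is label-correlated (each informative
#' column equals the class indicator with its bits flipped at `flip_prob`,
#' giving point-biserial correlation about `1 - 2 * flip_prob` on balanced
#' classes) and the remaining columns are independent background noise.
#' Count families receive non-negative integer values with the same
#' correlation structure.
#'
#' @param data Compound table with `id` and `true_class` columns.
#' @param name Registry family name.
#' @param signal_frac Fraction of columns carrying signal (0 for a null
#'   block).
#' @param flip_prob Per-bit flip rate of the informative columns.
#' @param background_rate Bernoulli rate of the noise bits.
#' @param seed Integer seed.
#' @return An `fp_block`; informative column indices are attached as
#'   attribute `"informative"`.
#' @export
gen_fp_block <- function(data, name, signal_frac = 0.05, flip_prob = 0.1,
                         background_rate = 0.1, seed = 1L) {
  entry <- registry_entry(name)
  y <- as_binary01(as.character(data$true_class))
  n <- length(y); w <- entry$width
  # the column structure (which columns carry signal) is a property of the
  # fabricated descriptor family, not of the compound set: draw it under its
  # own seed so blocks generated for different row subsets agree on it
  n_sig <- round(signal_frac * w)
  sig_cols <- if (n_sig > 0) {
    withr::with_seed(child_seed(seed, "columns"), sample(w, n_sig))
  } else integer(0)
  withr::with_seed(seed, {
    mat <- matrix(stats::rbinom(n * w, 1, background_rate), nrow = n)
    for (j in sig_cols) {
      flips <- stats::rbinom(n, 1, flip_prob)
      mat[, j] <- as.integer(xor(y == 1, flips == 1))
    }
    if (entry$value_kind == "count") {
      mat <- mat * (1L + stats::rpois(n * w, 1)) +
        stats::rpois(n * w, 0.2)
    }
  })
  colnames(mat) <- paste0(name, seq_len(w))
  block <- new_fp_block(name, mat, data$id)
  attr(block, "informative") <- sort(sig_cols)
  block
}

#' Write synthetic PaDEL-format fingerprint files
#'
#' @param data Compound table with `id` and `true_class`.
#' @param names Families to fabricate.
#' @param dir Output directory (created if needed).
#' @param ... Passed to [gen_fp_block()] (`signal_frac`, `flip_prob`, ...).
#' @param seed Integer seed; each family uses a child seed.
#' @return Named character vector of file paths, usable as `import_paths`.
#' @export
gen_imported_fp_files <- function(data, names, dir, ..., seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names, function(nm) {
    block <- gen_fp_block(data, nm, ..., seed = child_seed(seed, nm))
    path <- file.path(dir, paste0(nm, ".csv"))
    write_fp_block(block, path)
    path
  }, character(1))
  stats::setNames(paths, names)
}
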