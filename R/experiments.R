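# Desk-scale validation experiments on synthetic planted-motif data. These
# power both the test suite and the reproduction script: the planted-motif
# run checks that stacking and the two-step selector recover known signal;
# the null run calibrates the CV MCC noise floor.

# Fast singleton grids used by the experiments: one sensible parameter point
# per algorithm, so per-fold tuning reduces to a single fit.
experiment_grids <- function() {
  list(RF = list(mtry_mult = 1, num_trees = 300),
       GLM = list(lambda = 0.01),
       CART = list(cp = 0.01),
       KNN = list(k = 5),
       SVM = list(cost = 1, gamma_mult = 1),
       XGB = list(max_depth = 3, eta = 0.3, nrounds = 50),
       PLS = list(ncomp = 4),
       MLP = list(size = 5))
}

#' Planted-motif recovery experiment
#'
#' One full stacked run on a synthetic dataset with known signal: 600
#' compounds (default) whose actives carry fluorinated/tertiary-amine motifs,
#' 10% label noise, three descriptor families (native MACCS, which sees the
#' real motifs; an imported FP4 block with synthetic signal; an imported AP2D
#' block of pure noise) and four fast base algorithms. Reports each base
#' classifier's out-of-fold CV MCC, the meta-classifier's CV MCC on the
#' selected PF columns (fresh fold plan), and whether the selector recovered
#' every informative PF column (those fed by MACCS or FP4).
#'
#' @param seed Integer seed driving data generation, fold plans and fits.
#' @param n_active,n_inactive Class sizes.
#' @param label_noise Label-flip rate.
#' @param algorithms Base algorithms (default the four fast ones).
#' @param k Outer CV folds.
#' @return List: `base_cv` (tibble column/mcc), `best_base_cv_mcc`,
#'   `meta_cv_mcc`, `recovered`, `chosen_m`, `informative_columns`, `n`.
#' @export
planted_motif_experiment <- function(seed = 1L, n_active = 300L,
                                     n_inactive = 300L, label_noise = 0.1,
                                     algorithms = c("RF", "GLM", "CART", "KNN"),
                                     k = 10L) {
  spec <- synthetic_spec(n_active = n_active, n_inactive = n_inactive,
                         label_noise = label_noise,
                         seed = child_seed(seed, "data"))
  raw <- gen_labeled_smiles(spec)
  cur <- curate_compounds(raw)
  y <- as_binary01(as.character(cur$label))
  blocks <- list(
    MACCS = compute_fp(cur, "MACCS"),
    FP4 = gen_fp_block(dplyr::left_join(cur, raw[, c("id", "true_class")],
                                        by = "id"),
                       "FP4", signal_frac = 0.02, flip_prob = 0.3,
                       seed = child_seed(seed, "fp4")),
    AP2D = gen_fp_block(dplyr::left_join(cur, raw[, c("id", "true_class")],
                                         by = "id"),
                        "AP2D", signal_frac = 0, seed = child_seed(seed, "ap2d")))
  grids <- experiment_grids()
  specs <- enumerate_base_specs(algorithms, names(blocks))
  plan <- make_fold_plan(y, k = k, seed = child_seed(seed, "plan"))
  columns <- list()
  for (i in seq_len(nrow(specs))) {
    col <- specs$column[i]
    columns[[col]] <- out_of_fold_pf(specs$algorithm[i],
                                     blocks[[specs$descriptor[i]]], y, plan,
                                     grid = grids[[specs$algorithm[i]]],
                                     seed = child_seed(seed, col))
  }
  apf <- assemble_apf(columns)
  base_cv <- tibble(
    column = colnames(apf$matrix),
    mcc = apply(apf$matrix, 2, function(p)
      mcc_from_counts(confusion_counts(y, as.integer(p >= 0.5)))))
  ranking <- rank_importance(apf, y, seed = child_seed(seed, "rank"))
  sel <- select_opf(apf, y, ranking, grid = selection_grid(4, 12, 4),
                    k = k, seed = child_seed(seed, "select"))
  informative <- specs$column[specs$descriptor %in% c("MACCS", "FP4")]
  meta_fit_fun <- function(Xtr, ytr, s) {
    lf <- fit_learner("SVM", Xtr, ytr, list(cost = 1, gamma_mult = 1), s)
    function(Xte) predict_learner(lf, Xte)
  }
  meta_cv <- cross_validate(apf$matrix[, sel$chosen_columns, drop = FALSE], y,
                            meta_fit_fun, k = k,
                            seed = child_seed(seed, "metacv"))
  # "recovered" asks whether step 1 separated signal from noise: the PF
  # columns fed by the two informative descriptor families must all rank
  # above every column fed by the null family. (The CV argmax of step 2 need
  # not retain all of them: the four algorithms' PF columns per family are
  # deliberately redundant, so the optimal subset is smaller.)
  list(base_cv = base_cv,
       best_base_cv_mcc = max(base_cv$mcc),
       meta_cv_mcc = meta_cv$MCC,
       recovered = setequal(ranking[seq_along(informative)], informative),
       chosen_m = sel$chosen_m,
       informative_columns = informative,
       n = nrow(cur))
}

#' Null-signal calibration experiment
#'
#' Same shape as the planted-motif run but every fingerprint block is pure
#' noise (no label correlation anywhere), so every CV MCC estimate should sit
#' inside the sampling-noise band around zero.
#'
#' @param seed Integer seed.
#' @param n_active,n_inactive Class sizes.
#' @param algorithms Base algorithms.
#' @param k CV folds.
#' @return List: `base_cv` tibble, `meta_cv_mcc`, `all_mccs` (base and meta),
#'   `n`.
#' @export
null_signal_experiment <- function(seed = 1L, n_active = 300L,
                                   n_inactive = 300L,
                                   algorithms = c("RF", "GLM", "CART", "KNN"),
                                   k = 10L) {
  spec <- synthetic_spec(n_active = n_active, n_inactive = n_inactive,
                         label_noise = 0, seed = child_seed(seed, "data"))
  raw <- gen_labeled_smiles(spec)
  cur <- dplyr::left_join(curate_compounds(raw),
                          raw[, c("id", "true_class")], by = "id")
  y <- as_binary01(as.character(cur$label))
  fams <- c("FP4", "AP2D", "Pubchem")
  blocks <- stats::setNames(lapply(fams, function(nm)
    gen_fp_block(cur, nm, signal_frac = 0,
                 seed = child_seed(seed, paste0("null", nm)))), fams)
  grids <- experiment_grids()
  specs <- enumerate_base_specs(algorithms, fams)
  plan <- make_fold_plan(y, k = k, seed = child_seed(seed, "plan"))
  columns <- list()
  for (i in seq_len(nrow(specs))) {
    col <- specs$column[i]
    columns[[col]] <- out_of_fold_pf(specs$algorithm[i],
                                     blocks[[specs$descriptor[i]]], y, plan,
                                     grid = grids[[specs$algorithm[i]]],
                                     seed = child_seed(seed, col))
  }
  apf <- assemble_apf(columns)
  base_cv <- tibble(
    column = colnames(apf$matrix),
    mcc = apply(apf$matrix, 2, function(p)
      mcc_from_counts(confusion_counts(y, as.integer(p >= 0.5)))))
  ranking <- rank_importance(apf, y, seed = child_seed(seed, "rank"))
  sel <- select_opf(apf, y, ranking, grid = selection_grid(4, 12, 4),
                    k = k, seed = child_seed(seed, "select"))
  meta_fit_fun <- function(Xtr, ytr, s) {
    lf <- fit_learner("SVM", Xtr, ytr, list(cost = 1, gamma_mult = 1), s)
    function(Xte) predict_learner(lf, Xte)
  }
  meta_cv <- cross_validate(apf$matrix[, sel$chosen_columns, drop = FALSE], y,
                            meta_fit_fun, k = k,
                            seed = child_seed(seed, "metacv"))
  list(base_cv = base_cv, meta_cv_mcc = meta_cv$MCC,
       all_mccs = c(base_cv$mcc, meta_cv$MCC), n = nrow(cur))
}
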