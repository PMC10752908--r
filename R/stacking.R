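# Second stacking layer: out-of-fold probabilistic features (PFs), the
# all-PF matrix (APF), and the calibrated SVM meta-classifier (mSVM).
#
# PF semantics: the training rows are split once into k stratified folds; for
# each fold the base classifier is tuned and fitted on the complementary
# rows and predicts the held-out fold, so every training row is predicted
# exactly once by a model that never saw its label. The alternative
# "average" mode (each fold model predicts every row and the k outputs are
# averaged pointwise) is available behind a flag but leaks labels into 9 of
# 10 predictions per row and is not the default.

#' Generate one out-of-fold probabilistic-feature column
#'
#' @param algorithm Base algorithm code.
#' @param block `fp_block` aligned with `y`.
#' @param y Labels.
#' @param plan A [make_fold_plan()] fold plan for the same rows.
#' @param grid Hyperparameter grid for the per-fold tuning (defaults to
#'   [default_grid()]; a single-candidate grid skips inner tuning).
#' @param seed Integer seed.
#' @param mode `"concat"` (default; each row predicted once, out of fold) or
#'   `"average"` (pointwise mean of all fold models' predictions).
#' @param inner_k Folds for the per-fold hyperparameter tuning.
#' @param return_models Keep the k fold models as an attribute.
#' @return Numeric PF vector in \[0, 1\] with attribute `"fold_plan"`.
#' @export
out_of_fold_pf <- function(algorithm, block, y, plan,
                           grid = default_grid(algorithm), seed = 1L,
                           mode = c("concat", "average"), inner_k = 5L,
                           return_models = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(block, "fp_block"), inherits(plan, "fold_plan"))
  y01 <- as_binary01(y)
  n <- length(y01)
  if (nrow(block$matrix) != n || length(plan$assignment) != n) {
    abort("block, labels and fold plan must cover the same rows")
  }
  pf <- rep(NA_real_, n)
  avg <- matrix(NA_real_, nrow = n, ncol = plan$k)
  models <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- which(plan$assignment != f)
    te <- which(plan$assignment == f)
    if (length(unique(y01[tr])) < 2L) {
      # stratification repair: borrow one held-out row of the missing class
      missing_cls <- setdiff(c(0L, 1L), unique(y01[tr]))[1]
      borrow <- te[y01[te] == missing_cls][1]
      warn(sprintf("fold %d training part lacked class %d; borrowed one row",
                   f, missing_cls))
      tr <- c(tr, borrow)
    }
    sub_block <- new_fp_block(block$name,
                              block$matrix[tr, , drop = FALSE],
                              block$row_ids[tr])
    m <- tune_and_fit(algorithm, sub_block, y01[tr], grid = grid,
                      k = inner_k, seed = child_seed(seed, paste0("oof", f)))
    if (mode == "concat") {
      pf[te] <- predict_learner(m$fit, block$matrix[te, , drop = FALSE])
    } else {
      avg[, f] <- predict_learner(m$fit, block$matrix)
    }
    if (return_models) models[[f]] <- m
  }
  if (mode == "average") pf <- rowMeans(avg)
  attr(pf, "fold_plan") <- plan
  if (return_models) attr(pf, "fold_models") <- models
  pf
}

#' Assemble PF columns into a probabilistic-feature matrix
#'
#' Binds named PF columns (from [out_of_fold_pf()]) into an n x k matrix.
#' All columns must share the row count and the fold plan under which they
#' were generated; at the full 8x9 configuration the result is the 72-D APF.
#'
#' @param columns Named list of PF vectors (names `"ALGO__DESCRIPTOR"`).
#' @return A `pf_matrix`: list with `matrix` and `fold_plan`.
#' @export
assemble_apf <- function(columns) {
  if (!length(columns)) abort("no PF columns supplied")
  if (is.null(names(columns)) || any(!nzchar(names(columns)))) {
    abort("PF columns must be named ALGO__DESCRIPTOR")
  }
  n <- length(columns[[1]])
  plan <- attr(columns[[1]], "fold_plan")
  for (i in seq_along(columns)) {
    if (length(columns[[i]]) != n) {
      abort("alignment error: PF columns have different lengths")
    }
    p_i <- attr(columns[[i]], "fold_plan")
    if (!is.null(plan) && !is.null(p_i) && !fold_plans_equal(plan, p_i)) {
      abort("alignment error: PF columns were generated under different fold plans")
    }
  }
  mat <- do.call(cbind, lapply(columns, as.numeric))
  colnames(mat) <- names(columns)
  structure(list(matrix = mat, fold_plan = plan), class = "pf_matrix")
}

#' @method print pf_matrix
#' @export
print.pf_matrix <- function(x, ...) {
  cat(sprintf("<pf_matrix> %d compounds x %d probabilistic features\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Default meta-classifier hyperparameter grid
#'
#' RBF-kernel SVM grid: cost over \{0.1, 1, 10, 100\} and gamma over
#' \{1/p, 10/p\} where p is the number of selected PF columns.
#'
#' @return Named list of parameter vectors.
#' @export
default_meta_grid <- function() list(cost = c(0.1, 1, 10, 100),
                                     gamma_mult = c(1, 10))

#' Fit the SVM meta-classifier on selected PF columns
#'
#' Tunes an RBF SVM over `svm_grid` by stratified k-fold cross-validated MCC
#' on the PF matrix restricted to `selected`, then refits on all rows with
#' Platt-style probability calibration.
#'
#' @param pf A `pf_matrix` (or plain numeric matrix with column names).
#' @param y Labels.
#' @param selected Non-empty character vector of PF column names.
#' @param svm_grid Meta SVM grid (default [default_meta_grid()]).
#' @param k Tuning folds.
#' @param seed Integer seed.
#' @return A `meta_svm` object.
#' @export
fit_meta <- function(pf, y, selected, svm_grid = default_meta_grid(),
                     k = 10L, seed = 1L) {
  mat <- if (inherits(pf, "pf_matrix")) pf$matrix else as.matrix(pf)
  if (length(selected) == 0L) abort("`selected` must name at least one PF column")
  missing <- setdiff(selected, colnames(mat))
  if (length(missing)) {
    abort(sprintf("unknown PF column(s): %s", paste(missing, collapse = ", ")))
  }
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2L) abort("meta training labels contain a single class")
  X <- mat[, selected, drop = FALSE]
  block <- structure(list(name = "PF", matrix = X, value_kind = "real",
                          row_ids = rownames(X)), class = "fp_block")
  candidates <- grid_candidates(svm_grid)
  scores <- vapply(seq_along(candidates), function(i) {
    fit_fun <- function(Xtr, ytr, s) {
      lf <- fit_learner("SVM", Xtr, ytr, candidates[[i]], s)
      function(Xte) predict_learner(lf, Xte)
    }
    cross_validate(X, y01, fit_fun, k = k,
                   seed = child_seed(seed, "metatune"))$MCC
  }, numeric(1))
  tuned <- candidates[[which.max(scores)]]
  fit <- fit_learner("SVM", X, y01, tuned, child_seed(seed, "metafit"))
  structure(list(fit = fit, selected = selected, tuned_params = tuned,
                 tuning = tibble(candidate = seq_along(candidates),
                                 cv_mcc = scores),
                 seed = seed),
            class = "meta_svm")
}

#' Fit the full stacked ensemble
#'
#' End-to-end training on a curated training split: per (algorithm,
#' descriptor) pair, generate the out-of-fold PF column and refit the base
#' classifier on all training rows for deployment; assemble the APF; rank PF
#' columns by random-forest importance and select the optimal subset (OPF) by
#' the incremental top-m search; fit the SVM meta-classifier on the OPF.
#'
#' @param train Curated tibble (rows of the training split, with `label`).
#' @param blocks Named list of `fp_block`s row-aligned with `train`; the
#'   names define the enabled descriptor families.
#' @param algorithms Enabled base algorithms (default all eight).
#' @param grids Optional named list algorithm -> hyperparameter grid.
#' @param sel_grid A [selection_grid()] for the top-m search.
#' @param k Outer fold count for PF generation and CV scoring.
#' @param inner_k Folds for per-fold base tuning.
#' @param seed Integer master seed.
#' @param pf_mode `"concat"` or `"average"`, see [out_of_fold_pf()].
#' @return A `stacked_model`.
#' @export
fit_stacker <- function(train, blocks, algorithms = qsarstack::algorithms(),
                        grids = NULL, sel_grid = selection_grid(),
                        k = 10L, inner_k = 5L, seed = 1L,
                        pf_mode = c("concat", "average")) {
  pf_mode <- match.arg(pf_mode)
  if (nrow(train) == 0L) abort("empty training split")
  y01 <- as_binary01(as.character(train$label))
  specs <- enumerate_base_specs(algorithms, names(blocks))
  plan <- make_fold_plan(y01, k = k, seed = child_seed(seed, "plan"))
  columns <- list()
  base_models <- list()
  for (i in seq_len(nrow(specs))) {
    algo <- specs$algorithm[i]; desc <- specs$descriptor[i]
    col <- specs$column[i]
    grid <- (grids[[algo]]) %||% default_grid(algo)
    columns[[col]] <- out_of_fold_pf(
      algo, blocks[[desc]], y01, plan, grid = grid,
      seed = child_seed(seed, col), mode = pf_mode, inner_k = inner_k,
      return_models = (pf_mode == "average"))
    base_models[[col]] <- tune_and_fit(
      algo, blocks[[desc]], y01, grid = grid, k = inner_k,
      seed = child_seed(seed, paste0("full_", col)))
  }
  apf <- assemble_apf(columns)
  ranking <- rank_importance(apf, y01, seed = child_seed(seed, "rank"))
  sel <- select_opf(apf, y01, ranking, grid = sel_grid, k = k,
                    seed = child_seed(seed, "select"))
  meta <- fit_meta(apf, y01, sel$chosen_columns,
                   k = k, seed = child_seed(seed, "meta"))
  structure(list(base_models = base_models, apf = apf, fold_plan = plan,
                 selection = sel, meta = meta, specs = specs,
                 pf_mode = pf_mode,
                 pf_columns = if (pf_mode == "average") columns else NULL,
                 train_ids = train$id, y = y01, seed = seed),
            class = "stacked_model")
}

#' @method print stacked_model
#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf(paste0("<stacked_model> %d base classifiers (%d algorithms x %d ",
                     "descriptors); %d of %d PF columns selected; meta SVM ",
                     "cost=%g\n"),
              length(x$base_models),
              length(unique(x$specs$algorithm)),
              length(unique(x$specs$descriptor)),
              length(x$selection$chosen_columns), ncol(x$apf$matrix),
              x$meta$tuned_params$cost))
  invisible(x)
}

#' Predict activity for new compounds with a stacked model
#'
#' New-sample PFs are the probabilities of the base classifiers refit on the
#' full training split (or, under `pf_mode = "average"`, the mean over the k
#' fold models); the meta SVM is applied to the selected columns.
#'
#' @param object A `stacked_model`.
#' @param blocks Named list of `fp_block`s covering every descriptor used by
#'   the selected PF columns, row-aligned with each other.
#' @param ... Unused.
#' @return Tibble with `id`, `p_active`, `class` (`active`/`inactive`).
#' @export
predict.stacked_model <- function(object, blocks, ...) {
  sel <- object$selection$chosen_columns
  specs <- object$specs[object$specs$column %in% sel, , drop = FALSE]
  need <- unique(specs$descriptor)
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    abort(sprintf("missing fingerprint block(s): %s (configuration error)",
                  paste(missing, collapse = ", ")))
  }
  ids <- blocks[[need[1]]]$row_ids
  newpf <- matrix(NA_real_, nrow = length(ids), ncol = length(sel),
                  dimnames = list(ids, sel))
  for (i in seq_len(nrow(specs))) {
    col <- specs$column[i]
    blk <- blocks[[specs$descriptor[i]]]
    newpf[, col] <- if (object$pf_mode == "average") {
      fms <- attr(object$pf_columns[[col]], "fold_models")
      rowMeans(vapply(fms, function(m) predict_learner(m$fit, blk$matrix),
                      numeric(length(ids))))
    } else {
      predict_proba(object$base_models[[col]], blk)
    }
  }
  p <- predict_learner(object$meta$fit, newpf[, sel, drop = FALSE])
  tibble(id = ids, p_active = p,
         class = factor(ifelse(p >= 0.5, "active", "inactive"),
                        levels = c("active", "inactive")))
}
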