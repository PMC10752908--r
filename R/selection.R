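# Two-step feature selection over PF columns: (1) rank all columns by
# random-forest importance; (2) score nested top-m subsets by cross-validated
# MCC of an SVM and keep the best, preferring smaller subsets on ties.

#' Top-m search grid for feature selection
#'
#' Candidate subset sizes form the arithmetic sequence `m_start`,
#' `m_start + s`, ... up to `m_end`. The default (5, 70, 5) yields n = 14
#' candidate sizes.
#'
#' @param m_start First subset size (>= 1).
#' @param m_end Last subset size.
#' @param s Step between sizes (>= 1).
#' @return A `selection_grid` object with derived element `n`.
#' @export
selection_grid <- function(m_start = 5L, m_end = 70L, s = 5L) {
  if (m_start < 1L || s < 1L || m_end < m_start) {
    abort("require m_start >= 1, s >= 1, m_end >= m_start")
  }
  structure(list(m_start = as.integer(m_start), m_end = as.integer(m_end),
                 s = as.integer(s),
                 n = as.integer((m_end - m_start) %/% s + 1L)),
            class = "selection_grid")
}

#' Candidate subset sizes of a selection grid
#'
#' @param grid A [selection_grid()].
#' @param n_features Optional total feature count; sizes beyond it are
#'   clipped with a warning.
#' @return Integer vector of subset sizes.
#' @export
candidate_sizes <- function(grid, n_features = NULL) {
  stopifnot(inherits(grid, "selection_grid"))
  sizes <- seq.int(grid$m_start, grid$m_end, by = grid$s)
  if (!is.null(n_features) && any(sizes > n_features)) {
    warn(sprintf("clipping selection grid at the feature count (%d)", n_features))
    sizes <- sizes[sizes <= n_features]
    if (!length(sizes)) sizes <- as.integer(n_features)
  }
  as.integer(sizes)
}

#' Rank PF columns by random-forest importance
#'
#' Fits a 500-tree random forest on the full PF matrix and sorts the columns
#' by decreasing importance (impurity-decrease by default; permutation
#' importance via `type`). Ties break by column order.
#'
#' @param pf A `pf_matrix` or numeric matrix with column names.
#' @param y Labels.
#' @param seed Integer seed.
#' @param type `"impurity"` or `"permutation"`.
#' @param num_trees Number of trees.
#' @return Character vector: all column names, most important first.
#' @export
rank_importance <- function(pf, y, seed = 1L,
                            type = c("impurity", "permutation"),
                            num_trees = 500L) {
  type <- match.arg(type)
  mat <- if (inherits(pf, "pf_matrix")) pf$matrix else as.matrix(pf)
  y01 <- as_binary01(y)
  if (length(unique(y01)) < 2L) abort("importance ranking needs both classes")
  rf <- ranger::ranger(x = mat, y = factor(y01, levels = c(0, 1)),
                       num.trees = num_trees, importance = type,
                       num.threads = 1L, seed = seed)
  imp <- rf$variable.importance[colnames(mat)]
  colnames(mat)[order(-imp, seq_along(imp))]
}

#' Select the optimal PF subset (OPF)
#'
#' For each candidate size m, an RBF SVM on the top-m ranked columns is
#' scored by stratified k-fold cross-validated MCC; one fold plan (derived
#' from `seed`) is shared across all m so that score differences reflect the
#' feature sets, not fold resampling. The chosen m is the argmax, ties
#' resolving to the smaller size. The scoring SVM uses fixed parameters
#' (cost 1, gamma 1/m); the deployed meta-classifier is grid-tuned
#' separately by [fit_meta()].
#'
#' @param pf A `pf_matrix` or numeric matrix.
#' @param y Labels.
#' @param ranking Column ranking from [rank_importance()]; must cover the PF
#'   columns.
#' @param grid A [selection_grid()].
#' @param k CV folds.
#' @param seed Integer seed.
#' @param cost SVM cost used for subset scoring.
#' @return A `selection_result`: `ranking`, `per_m` (tibble of m and CV MCC),
#'   `chosen_m`, `chosen_columns`.
#' @export
select_opf <- function(pf, y, ranking, grid = selection_grid(), k = 10L,
                       seed = 1L, cost = 1) {
  mat <- if (inherits(pf, "pf_matrix")) pf$matrix else as.matrix(pf)
  y01 <- as_binary01(y)
  if (!setequal(ranking, colnames(mat))) {
    abort("`ranking` must be a permutation of the PF column names")
  }
  sizes <- candidate_sizes(grid, n_features = ncol(mat))
  plan <- make_fold_plan(y01, k = k, seed = child_seed(seed, "selplan"))
  mccs <- vapply(sizes, function(m) {
    cols <- ranking[seq_len(m)]
    X <- mat[, cols, drop = FALSE]
    oof <- rep(NA_real_, length(y01))
    for (f in seq_len(k)) {
      tr <- which(plan$assignment != f); te <- which(plan$assignment == f)
      lf <- fit_learner("SVM", X[tr, , drop = FALSE], y01[tr],
                        list(cost = cost, gamma_mult = 1),
                        child_seed(seed, paste0("sel", m, "_", f)))
      oof[te] <- predict_learner(lf, X[te, , drop = FALSE])
    }
    mcc_from_counts(confusion_counts(y01, as.integer(oof >= 0.5)))
  }, numeric(1))
  best <- which.max(mccs)  # sizes ascend, so ties pick the smaller m
  structure(list(ranking = ranking,
                 per_m = tibble(m = sizes, cv_mcc = mccs),
                 chosen_m = sizes[best],
                 chosen_columns = ranking[seq_len(sizes[best])],
                 grid = grid, seed = seed),
            class = "selection_result")
}

#' @method print selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> chose m = %d of %d PF columns (CV MCC %.3f)\n",
              x$chosen_m, length(x$ranking),
              x$per_m$cv_mcc[x$per_m$m == x$chosen_m]))
  invisible(x)
}
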