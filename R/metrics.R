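# Six-metric evaluation: ACC, BACC, Sn, Sp, MCC, AUC, with cross-validation
# and independent-test harnesses. Active is the positive class throughout and
# the classification threshold is fixed at 0.5.

#' Confusion counts for binary predictions
#'
#' @param y_true True labels (factor `active`/`inactive`, logical, or 0/1).
#' @param y_pred Predicted labels, same encodings accepted.
#' @return A list with integer elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length")
  }
  yt <- as_binary01(y_true); yp <- as_binary01(y_pred)
  list(TP = sum(yt == 1 & yp == 1), TN = sum(yt == 0 & yp == 0),
       FP = sum(yt == 0 & yp == 1), FN = sum(yt == 1 & yp == 0))
}

mcc_from_counts <- function(cc) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  # degenerate marginals (a row or column of the table is empty): MCC := 0
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Rank-based AUC
#'
#' The area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic: the probability that a uniformly chosen active outscores a
#' uniformly chosen inactive, ties counting one half. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores (higher = more active).
#' @param y_true True labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, y_true) {
  yt <- as_binary01(y_true)
  n_pos <- sum(yt == 1); n_neg <- sum(yt == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC requires both classes present")
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[yt == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compute the six performance metrics
#'
#' Given true labels and either hard predictions, probability scores, or
#' both, computes ACC, BACC, Sn, Sp, MCC and (when scores are supplied) AUC.
#' With scores only, hard classes are `score >= 0.5`. MCC is defined as 0
#' when any marginal of the confusion table is empty. Sn/Sp are NA when the
#' corresponding class is absent.
#'
#' @param y_true True labels.
#' @param y_pred Optional hard predictions.
#' @param scores Optional probability scores for the active class.
#' @param context `"cross_validation"` or `"independent_test"` (bookkeeping).
#' @return A one-row tibble: context, TP/TN/FP/FN, ACC, BACC, Sn, Sp, MCC,
#'   AUC.
#' @export
compute_metrics <- function(y_true, y_pred = NULL, scores = NULL,
                            context = c("cross_validation", "independent_test")) {
  context <- match.arg(context)
  if (is.null(y_pred)) {
    if (is.null(scores)) abort("supply `y_pred` and/or `scores`")
    y_pred <- as.integer(scores >= 0.5)
  }
  cc <- confusion_counts(y_true, y_pred)
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  sn <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  sp <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, y_true)
  tibble(context = context,
         TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
         ACC = if (n > 0) (cc$TP + cc$TN) / n else NA_real_,
         BACC = (sn + sp) / 2,
         Sn = sn, Sp = sp,
         MCC = mcc_from_counts(cc),
         AUC = auc)
}

#' Cross-validate an arbitrary probabilistic classifier
#'
#' Runs one stratified k-fold plan and scores the pooled out-of-fold
#' predictions once (micro-averaging, the default) or averages per-fold
#' metrics (macro). `fit_fun(X_train, y_train, seed)` must return a
#' `function(X_new)` yielding P(active).
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param fit_fun Model builder, see Details.
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold plan and per-fold fits.
#' @param scoring `"pooled"` or `"macro"`.
#' @return A one-row metrics tibble (context `cross_validation`); the pooled
#'   out-of-fold scores are attached as attribute `"oof_scores"`.
#' @export
cross_validate <- function(X, y, fit_fun, k = 10L, seed = 1L,
                           scoring = c("pooled", "macro")) {
  scoring <- match.arg(scoring)
  y01 <- as_binary01(y)
  plan <- make_fold_plan(y01, k = k, seed = seed)
  oof <- rep(NA_real_, length(y01))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(plan$assignment == f)
    tr <- which(plan$assignment != f)
    predict_fun <- fit_fun(X[tr, , drop = FALSE], y01[tr],
                           child_seed(seed, paste0("cvfold", f)))
    oof[te] <- predict_fun(X[te, , drop = FALSE])
    if (scoring == "macro") {
      per_fold[[f]] <- compute_metrics(y01[te], scores = oof[te])
    }
  }
  out <- if (scoring == "pooled") {
    compute_metrics(y01, scores = oof)
  } else {
    agg <- dplyr::bind_rows(per_fold) |>
      dplyr::summarise(dplyr::across(c("ACC", "BACC", "Sn", "Sp", "MCC", "AUC"),
                                     ~ mean(.x, na.rm = TRUE)))
    cc <- confusion_counts(y01, as.integer(oof >= 0.5))
    dplyr::bind_cols(tibble(context = "cross_validation",
                            TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN), agg)
  }
  attr(out, "oof_scores") <- oof
  out
}

#' Evaluate a stacked model on an independent test split
#'
#' Guards against train/test leakage by asserting that no test compound id
#' appears in the model's training set, then scores the held-out split in a
#' single pass.
#'
#' @param model A `stacked_model` from [fit_stacker()].
#' @param test Curated tibble of held-out compounds (with `label`).
#' @param blocks Named list of `fp_block`s covering the model's descriptors,
#'   row-aligned with `test`.
#' @return A one-row metrics tibble (context `independent_test`).
#' @export
evaluate_independent <- function(model, test, blocks) {
  if (nrow(test) == 0L) abort("empty test set")
  overlap <- intersect(test$id, model$train_ids)
  if (length(overlap)) {
    abort(sprintf("leakage error: %d test id(s) were used in training (e.g. %s)",
                  length(overlap), overlap[1]))
  }
  pred <- predict(model, blocks = blocks)
  compute_metrics(as_binary01(as.character(test$label)),
                  scores = pred$p_active, context = "independent_test")
}
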