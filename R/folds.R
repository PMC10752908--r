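# Stratified cross-validation fold plans.

#' Build a stratified k-fold plan
#'
#' Rows are partitioned into `k` folds, stratified by class so that within
#' each class fold sizes differ by at most one. The assignment is a pure
#' function of `(y, k, seed)`.
#'
#' @param y Labels (any binary encoding).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, integer `assignment` (one fold index
#'   per row) and `seed`.
#' @export
make_fold_plan <- function(y, k = 10L, seed = 1L) {
  y01 <- as_binary01(y)
  n <- length(y01)
  if (k > n) abort(sprintf("k = %d exceeds the number of rows (%d)", k, n))
  if (k < 2L) abort("k must be at least 2")
  assignment <- integer(n)
  load <- integer(k)  # total fold sizes so far, to spread per-class remainders
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y01 == cls)
      if (!length(idx)) abort("both classes must be present to stratify folds")
      shuffled <- sample(idx)
      fold_order <- order(load, seq_len(k))
      folds <- rep_len(fold_order, length(idx))
      assignment[shuffled] <- folds
      load <- load + tabulate(folds, nbins = k)
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

fold_plans_equal <- function(a, b) {
  a$k == b$k && identical(a$assignment, b$assignment)
}
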