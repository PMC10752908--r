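# First stacking layer: one grid-tuned classifier per (algorithm, descriptor)
# pair; at the full configuration of 8 algorithms x 9 fingerprint families
# this yields the 72-classifier base matrix.

#' Enumerate base-classifier specifications
#'
#' The fixed (algorithm outer, descriptor inner) enumeration that defines
#' both the number of base classifiers and the column order of the
#' probabilistic-feature matrix. The full configuration (8 algorithms, 9
#' descriptor families) yields 72 specifications.
#'
#' @param algorithms Character vector of algorithm codes (default all eight).
#' @param descriptors Character vector of registry family names (default all
#'   nine).
#' @return Tibble with columns `algorithm`, `descriptor`, `column`
#'   (`"ALGO__DESCRIPTOR"`).
#' @export
enumerate_base_specs <- function(algorithms = qsarstack::algorithms(),
                                 descriptors = fp_registry()$name) {
  bad <- setdiff(algorithms, .ALGORITHMS)
  if (length(bad)) abort(sprintf("unknown algorithm(s): %s", paste(bad, collapse = ", ")))
  for (d in descriptors) registry_entry(d)
  tidyr::expand_grid(algorithm = algorithms, descriptor = descriptors) |>
    dplyr::mutate(column = paste0(.data$algorithm, "__", .data$descriptor))
}

#' Grid-tune and fit one base classifier
#'
#' Every point of the hyperparameter grid is scored by stratified k-fold
#' cross-validated MCC on the training rows (pooled out-of-fold scoring); the
#' argmax is retained, ties resolving to the first candidate in enumeration
#' order, and the model is refit on all rows with the tuned parameters. A
#' single-candidate grid skips the scoring pass.
#'
#' @param algorithm One of [algorithms()].
#' @param block An `fp_block` whose rows align with `y`.
#' @param y Labels (both classes must be present).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @param k Tuning cross-validation folds.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A `base_model`: algorithm, descriptor, `tuned_params`, fitted
#'   predictor, and (when tuning ran) the tuning CV MCC per candidate.
#' @export
tune_and_fit <- function(algorithm, block, y, grid = default_grid(algorithm),
                         k = 10L, seed = 1L) {
  stopifnot(inherits(block, "fp_block"))
  y01 <- as_binary01(y)
  if (nrow(block$matrix) != length(y01)) {
    abort("fingerprint block rows do not align with the label vector")
  }
  candidates <- grid_candidates(grid)
  tuning <- NULL
  if (length(candidates) == 1L) {
    tuned <- candidates[[1]]
  } else {
    scores <- vapply(seq_along(candidates), function(i) {
      fit_fun <- function(Xtr, ytr, s) {
        lf <- fit_learner(algorithm, Xtr, ytr, candidates[[i]], s)
        function(Xte) predict_learner(lf, Xte)
      }
      cross_validate(block$matrix, y01, fit_fun, k = k,
                     seed = child_seed(seed, "tune"))$MCC
    }, numeric(1))
    best <- which.max(scores)  # first index on ties
    tuned <- candidates[[best]]
    tuning <- tibble(candidate = seq_along(candidates), cv_mcc = scores)
  }
  fit <- fit_learner(algorithm, block$matrix, y01, tuned,
                     child_seed(seed, "fullfit"))
  structure(list(algorithm = algorithm, descriptor = block$name,
                 tuned_params = tuned, fit = fit, tuning = tuning,
                 grid = grid, seed = seed),
            class = "base_model")
}

#' @method print base_model
#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s on %s; params: %s\n", x$algorithm, x$descriptor,
              paste(names(x$tuned_params), unlist(x$tuned_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predict activity probabilities with a base classifier
#'
#' @param model A `base_model`.
#' @param block An `fp_block` of the same descriptor family.
#' @return Numeric vector of P(active), one per row of the block.
#' @export
predict_proba <- function(model, block) {
  stopifnot(inherits(model, "base_model"), inherits(block, "fp_block"))
  if (block$name != model$descriptor) {
    abort(sprintf("descriptor mismatch: model is %s, block is %s",
                  model$descriptor, block$name))
  }
  predict_learner(model$fit, block$matrix)
}
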