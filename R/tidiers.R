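# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble with one row per candidate subset size: `m`, `cv_mcc`,
#'   `chosen`.
#' @export
tidy.selection_result <- function(x, ...) {
  x$per_m |>
    dplyr::mutate(chosen = .data$m == x$chosen_m)
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(n_features = length(x$ranking), chosen_m = x$chosen_m,
         best_cv_mcc = x$per_m$cv_mcc[x$per_m$m == x$chosen_m],
         m_start = x$grid$m_start, m_end = x$grid$m_end, s = x$grid$s)
}

#' Tidy a base classifier
#'
#' @param x A `base_model`.
#' @param ... Unused.
#' @return One row per tuning candidate (or the tuned point for singleton
#'   grids).
#' @export
tidy.base_model <- function(x, ...) {
  params <- tibble::as_tibble(x$tuned_params)
  if (is.null(x$tuning)) {
    dplyr::bind_cols(tibble(algorithm = x$algorithm, descriptor = x$descriptor),
                     params)
  } else {
    cands <- dplyr::bind_rows(lapply(grid_candidates(x$grid), tibble::as_tibble))
    dplyr::bind_cols(tibble(algorithm = x$algorithm, descriptor = x$descriptor,
                            candidate = seq_len(nrow(cands))),
                     cands, tibble(cv_mcc = x$tuning$cv_mcc))
  }
}

#' Tidy a stacked model
#'
#' @param x A `stacked_model`.
#' @param ... Unused.
#' @return One row per base classifier: `column`, `algorithm`, `descriptor`,
#'   whether its PF column was selected, and its tuned parameters as a
#'   compact string.
#' @export
tidy.stacked_model <- function(x, ...) {
  x$specs |>
    dplyr::mutate(
      selected = .data$column %in% x$selection$chosen_columns,
      tuned = vapply(x$base_models[.data$column], function(m)
        paste(names(m$tuned_params), unlist(m$tuned_params),
              sep = "=", collapse = ", "), character(1)))
}

#' @rdname tidy.stacked_model
#' @export
glance.stacked_model <- function(x, ...) {
  tibble(n_base = length(x$base_models),
         n_algorithms = length(unique(x$specs$algorithm)),
         n_descriptors = length(unique(x$specs$descriptor)),
         apf_width = ncol(x$apf$matrix),
         chosen_m = x$selection$chosen_m,
         meta_cost = x$meta$tuned_params$cost,
         meta_gamma_mult = x$meta$tuned_params$gamma_mult,
         n_train = length(x$train_ids),
         k = x$fold_plan$k, seed = x$seed)
}
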