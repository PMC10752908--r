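# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the top-m selection curve
#'
#' Cross-validated MCC against candidate subset size, with the chosen size
#' highlighted.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$cv_mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#D55E00"),
                                 guide = "none") +
    ggplot2::labs(x = "top-m PF columns", y = "cross-validated MCC",
                  title = sprintf("Two-step selection: m = %d chosen",
                                  object$chosen_m)) +
    ggplot2::theme_minimal()
}

#' Plot per-base-classifier cross-validation performance
#'
#' Heatmap of a metric over the algorithm x descriptor matrix, from a tibble
#' such as the `base_cv` element of [planted_motif_experiment()] (columns
#' `column` = `"ALGO__DESCRIPTOR"` and `mcc`).
#'
#' @param base_cv Tibble with `column` and `mcc`.
#' @return A ggplot.
#' @export
plot_base_matrix <- function(base_cv) {
  df <- base_cv |>
    tidyr::separate_wider_delim("column", "__",
                                names = c("algorithm", "descriptor"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$descriptor, y = .data$algorithm,
                                   fill = .data$mcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mcc)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), name = "CV MCC") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Base-classifier cross-validated MCC") +
    ggplot2::theme_minimal()
}
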