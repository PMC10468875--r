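#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-trait group comparison
#'
#' Dot plot of the focal-minus-reference median difference per trait,
#' coloured by direction and annotated with significance stars.
#'
#' @param comparison Tibble from [compare_traits()].
#' @return A ggplot.
#' @export
plot_group_comparison <- function(comparison) {
  d <- comparison |>
    mutate(delta = .data$median_focal - .data$median_other)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$trait,
                                                     .data$delta),
                                  y = .data$delta,
                                  colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Median difference (focal - reference)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
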