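#' Volcano plot of age-association results
#'
#' @param results Tibble from [fit_age_association()] /
#'   [call_differential()].
#' @param fdr_max,min_abs_log2fc Thresholds drawn as guides.
#' @return A ggplot.
#' @export
plot_volcano <- function(results, fdr_max = 0.05, min_abs_log2fc = 1) {
  d <- mutate(as_tibble(results),
              called = if ("called" %in% names(results)) .data$called
                       else .data$fdr < fdr_max &
                            abs(.data$log2fc_span) > min_abs_log2fc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc_span,
                                  y = -log10(pmax(.data$p, 1e-300)),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-min_abs_log2fc, min_abs_log2fc),
                        linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change over the age span",
                  y = expression(-log[10]~p), colour = "differential") +
    ggplot2::theme_minimal()
}

#' Plot top MAG-ranked genes
#'
#' Total MAG score against final conservation rank for the strongest
#' genes, coloured by consensus direction.
#'
#' @param mag MAG tibble from [mag_scores()].
#' @param top Number of top-ranked genes to show.
#' @return A ggplot.
#' @export
plot_mag_scores <- function(mag, top = 25) {
  d <- head(arrange(as_tibble(mag), .data$final_rank), top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, -.data$mag), y = .data$mag,
    fill = .data$consensus_direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "MAG score (sum over tissues)",
                  fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 60, hjust = 1))
}
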