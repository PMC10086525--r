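#' Linear age trends of cell-type composition
#'
#' For each cell type within each strain x tissue stratum, fits an
#' ordinary least-squares regression of percentage on age in months and
#' reports the slope (percent per month), its standard error, the
#' two-sided t-test p-value, and BH-adjusted FDR across the cell types
#' of the stratum. Degenerate zero-residual fits return the exact slope
#' with the p-value flagged unavailable (NA).
#'
#' @param table Long tibble: animal_id, strain, tissue, age_months,
#'   sex, cell_type, percent.
#' @param fdr_max Significance flag threshold on the FDR.
#' @return Tibble: strain, tissue, stratum, cell_type, slope, se, p,
#'   fdr, n, significant.
#' @export
#' @examples
#' d <- tibble::tibble(animal_id = 1:4, strain = "B6", tissue = "PBL",
#'                     age_months = c(3, 3, 18, 18), sex = "F",
#'                     cell_type = "B", percent = c(10, 10, 20, 20))
#' fit_composition_trends(d)
fit_composition_trends <- function(table, fdr_max = 0.05) {
  req <- c("strain", "tissue", "age_months", "cell_type", "percent")
  stopifnot(all(req %in% names(table)))
  out <- table |>
    group_by(.data$strain, .data$tissue, .data$cell_type) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$age_months)) < 2) {
        abort(sprintf("Stratum %s has a single age; slope not estimable.",
                      stratum_label(key$strain, key$tissue)))
      }
      if (nrow(d) < 3) {
        abort(sprintf("Stratum %s / %s has fewer than 3 animals.",
                      stratum_label(key$strain, key$tissue),
                      key$cell_type))
      }
      fit <- lm(percent ~ age_months, data = d)
      # zero-residual fits are handled explicitly below; silence the
      # "essentially perfect fit" advisory from summary.lm
      sm <- suppressWarnings(summary(fit))$coefficients
      slope <- sm["age_months", "Estimate"]
      rss <- sum(stats::residuals(fit)^2)
      if (rss < 1e-12 * max(1, sum(d$percent^2))) {
        # perfect fit: slope exact, no sampling variability to test
        tibble(slope = slope, se = 0, p = NA_real_, n = nrow(d))
      } else {
        tibble(slope = slope, se = sm["age_months", "Std. Error"],
               p = sm["age_months", "Pr(>|t|)"], n = nrow(d))
      }
    }) |>
    ungroup() |>
    mutate(stratum = stratum_label(.data$strain, .data$tissue))
  out |>
    group_by(.data$stratum) |>
    mutate(fdr = {
      ok <- !is.na(.data$p)
      f <- rep(NA_real_, n())
      f[ok] <- bh_adjust(.data$p[ok])
      f
    }) |>
    ungroup() |>
    mutate(significant = !is.na(.data$fdr) & .data$fdr < fdr_max) |>
    select("strain", "tissue", "stratum", "cell_type", "slope", "se",
           "p", "fdr", "n", "significant")
}

#' Plot composition age trends
#'
#' Percentage against age per cell type, with the fitted linear trend.
#'
#' @param table Long composition tibble (as for
#'   [fit_composition_trends()]).
#' @return A ggplot faceted by cell type.
#' @export
plot_composition_trends <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$age_months, y = .data$percent,
                               colour = .data$strain)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type),
                        scales = "free_y") +
    ggplot2::labs(x = "Age (months)", y = "Cell-type percentage") +
    ggplot2::theme_minimal()
}
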