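#' Rank features within a stratum by age-association significance
#'
#' Ranks ascending by p-value (rank 1 = most significant), breaking ties
#' by larger absolute log2 fold-change and then lexicographic feature
#' id, so the ranking is fully deterministic.
#'
#' @param results Per-feature age-association tibble (needs `feature`,
#'   `p`, `log2fc_span`).
#' @return Tibble feature / rank / n_tested / direction (sign of the
#'   fold change), carrying stratum/strain/tissue columns if present.
#' @export
rank_stratum <- function(results) {
  if (nrow(results) == 0) abort("Cannot rank an empty result table.")
  if (anyDuplicated(results$feature)) {
    abort("Duplicate feature ids in the result table.")
  }
  ord <- order(results$p, -abs(results$log2fc_span), results$feature)
  out <- results[ord, , drop = FALSE]
  out <- mutate(as_tibble(out),
                rank = row_number(),
                n_tested = n(),
                direction = sign(.data$log2fc_span))
  keep <- intersect(c("feature", "rank", "n_tested", "direction",
                      "stratum", "strain", "tissue"), names(out))
  out[, keep]
}

#' MAG conservation scores across strains and tissues
#'
#' The magnitude-of-association (MAG) score aggregates per-stratum
#' significance ranks: per tissue \eqn{t},
#' \deqn{m_t(g) = \Big(\prod_{s \in \mathrm{strains}} 1/r_{g,s,t}\Big)^{1/S},}
#' the geometric mean of inverse ranks across strains, and the total
#' score \eqn{M_g = \sum_t m_t(g)} sums over tissues. Genes absent from
#' a stratum (e.g. filtered out) receive the worst-plus-one rank
#' `n_tested + 1` there, so non-conservation is penalised rather than
#' dropped; set `absent_rank = "drop"` to restrict to genes tested in
#' every stratum instead. The final ranking descends on \eqn{M_g} with
#' lexicographic tie-breaks. The consensus direction is the common sign
#' of the per-stratum fold changes ("up", "down", or "mixed").
#'
#' @param rank_tables Tibble concatenating [rank_stratum()] outputs,
#'   with `strain` and `tissue` columns identifying each stratum.
#' @param strains,tissues Expected design; defaults to the values
#'   present. Every (strain, tissue) pair must have a rank table.
#' @param absent_rank `"worst_plus_one"` (default) or `"drop"`.
#' @return Tibble: feature, one `m_<tissue>` column per tissue, mag
#'   (total M), final_rank, consensus_direction.
#' @export
mag_scores <- function(rank_tables, strains = NULL, tissues = NULL,
                       absent_rank = c("worst_plus_one", "drop")) {
  absent_rank <- match.arg(absent_rank)
  stopifnot(all(c("feature", "rank", "n_tested", "strain", "tissue")
                %in% names(rank_tables)))
  if (is.null(strains)) strains <- unique(rank_tables$strain)
  if (is.null(tissues)) tissues <- unique(rank_tables$tissue)
  need <- tidyr::expand_grid(strain = strains, tissue = tissues)
  have <- distinct(rank_tables, .data$strain, .data$tissue)
  missing <- anti_join(need, have, by = c("strain", "tissue"))
  if (nrow(missing) > 0) {
    abort(sprintf("Missing rank tables for strata: %s",
                  paste(stratum_label(missing$strain, missing$tissue),
                        collapse = ", ")))
  }
  rank_tables <- inner_join(rank_tables, need, by = c("strain", "tissue"))
  genes <- sort(unique(rank_tables$feature))
  n_tested <- distinct(rank_tables, .data$strain, .data$tissue,
                       .data$n_tested)

  full <- tidyr::expand_grid(feature = genes, need) |>
    left_join(rank_tables[, c("feature", "strain", "tissue", "rank",
                              intersect("direction", names(rank_tables)))],
              by = c("feature", "strain", "tissue")) |>
    left_join(n_tested, by = c("strain", "tissue"))
  if (absent_rank == "drop") {
    tested_everywhere <- full |>
      group_by(.data$feature) |>
      summarise(ok = !anyNA(.data$rank), .groups = "drop") |>
      filter(.data$ok)
    full <- filter(full, .data$feature %in% tested_everywhere$feature)
    if (nrow(full) == 0) abort("No gene was tested in every stratum.")
  } else {
    full <- mutate(full,
                   rank = ifelse(is.na(.data$rank),
                                 .data$n_tested + 1, .data$rank))
  }

  per_tissue <- full |>
    group_by(.data$feature, .data$tissue) |>
    summarise(m = exp(mean(log(1 / .data$rank))), .groups = "drop")
  wide <- tidyr::pivot_wider(per_tissue, names_from = "tissue",
                             values_from = "m", names_prefix = "m_")
  totals <- per_tissue |>
    group_by(.data$feature) |>
    summarise(mag = sum(.data$m), .groups = "drop")

  dir_tbl <- if ("direction" %in% names(full)) {
    full |>
      filter(!is.na(.data$direction)) |>
      group_by(.data$feature) |>
      summarise(consensus_direction = dplyr::case_when(
        all(.data$direction > 0) ~ "up",
        all(.data$direction < 0) ~ "down",
        TRUE ~ "mixed"), .groups = "drop")
  } else {
    tibble(feature = genes, consensus_direction = NA_character_)
  }

  out <- wide |>
    left_join(totals, by = "feature") |>
    left_join(dir_tbl, by = "feature") |>
    arrange(dplyr::desc(.data$mag), .data$feature) |>
    mutate(final_rank = row_number())
  out
}

# Running-sum ES for hit positions `pos` (sorted) in a list of length N
# with hit weights `w` (same order as pos). Returns max of the running
# sum (0 if never positive) and the index where the max is attained.
gsea_es_from_hits <- function(pos, w, N) {
  k <- length(pos)
  miss_step <- 1 / (N - k)
  W <- sum(w)
  run_at_hit <- cumsum(w) / W - (pos - seq_len(k)) * miss_step
  es <- max(c(0, run_at_hit))
  list(es = es, argmax = if (es > 0) pos[which.max(run_at_hit)] else 0L)
}

#' Preranked gene set enrichment on the MAG ranking
#'
#' Walks the MAG-descending gene list; set members (hits) increment the
#' running sum by \eqn{|M_g|^w / \sum_{set} |M|^w} and non-members
#' decrement it by \eqn{1/(N - n_{set})}. The enrichment score ES is the
#' maximum of the running sum (enrichment at the top; 0 if the sum never
#' rises above zero). The null distribution places the set labels
#' uniformly at random on the list (gene-label permutation);
#' `p = (1 + #\{ES_null >= ES\}) / (1 + n_perm)` and
#' `NES = ES / mean(positive null ES)`. When `exhaustive = TRUE` and
#' `choose(N, n_set) <= 1e5` all placements are enumerated instead of
#' sampled, and `n_perm` becomes the number of placements. The leading
#' edge is the set members at or before the running-sum maximum.
#'
#' @param mag MAG table from [mag_scores()] (or any tibble with
#'   `feature` and a score column sorted into the ranking by
#'   descending score).
#' @param gene_set Character vector of member features.
#' @param weight_exponent Hit-weight exponent on |M| (0 = unweighted).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Seed for the permutation null.
#' @param exhaustive Enumerate all placements when feasible.
#' @param score_col Column holding the ranking score.
#' @return A `magsig_gsea` object: list with es, nes, p, n_perm, seed,
#'   leading_edge, gene_set, n_ranked, and a `running` tibble
#'   (position, running_sum, hit) for plotting.
#' @export
preranked_gsea <- function(mag, gene_set, weight_exponent = 1,
                           n_perm = 10000, seed = 1, exhaustive = FALSE,
                           score_col = "mag") {
  stopifnot("feature" %in% names(mag), score_col %in% names(mag))
  ranked <- arrange(as_tibble(mag), dplyr::desc(.data[[score_col]]),
                    .data$feature)
  genes <- ranked$feature
  score <- abs(ranked[[score_col]])
  N <- length(genes)
  hits <- genes %in% gene_set
  k <- sum(hits)
  if (k == 0) abort("Gene set has empty intersection with the ranked list.")
  if (k == N) abort("Gene set covers the whole ranked list; ES undefined.")

  w_all <- score^weight_exponent
  pos_obs <- which(hits)
  obs <- gsea_es_from_hits(pos_obs, w_all[pos_obs], N)

  # running sum trace for plotting / leading edge
  step <- rep(-1 / (N - k), N)
  step[hits] <- w_all[hits] / sum(w_all[hits])
  running <- cumsum(step)

  null_es <- NULL
  if (exhaustive) {
    if (choose(N, k) > 1e5) {
      abort("Exhaustive enumeration infeasible: choose(N, n_set) > 1e5.")
    }
    placements <- combn(N, k)
    null_es <- apply(placements, 2, function(pp) {
      gsea_es_from_hits(pp, w_all[pp], N)$es
    })
    n_perm <- ncol(placements)
  } else {
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        pp <- sort(sample.int(N, k))
        gsea_es_from_hits(pp, w_all[pp], N)$es
      }, numeric(1))
    })
  }
  # ties at the observed ES count as at-least-as-extreme; the 1e-12
  # tolerance keeps mathematically tied placements together despite
  # floating-point summation order
  pval <- (1 + sum(null_es >= obs$es - 1e-12)) / (1 + n_perm)
  pos_null <- null_es[null_es > 1e-12]
  nes <- if (length(pos_null) > 0) obs$es / mean(pos_null) else NA_real_

  leading <- if (obs$argmax > 0) genes[pos_obs[pos_obs <= obs$argmax]]
             else character(0)
  structure(list(
    es = obs$es, nes = nes, p = pval, n_perm = n_perm, seed = seed,
    weight_exponent = weight_exponent, exhaustive = exhaustive,
    leading_edge = leading, gene_set = intersect(gene_set, genes),
    n_ranked = N,
    running = tibble(position = seq_len(N), feature = genes,
                     running_sum = running, hit = hits)),
    class = "magsig_gsea")
}

#' @export
print.magsig_gsea <- function(x, ...) {
  cat(sprintf(
    "Preranked GSEA: ES = %.4f, NES = %.4f, p = %.4g (%d permutations)\n",
    x$es, x$nes, x$p, x$n_perm))
  cat(sprintf("Leading edge (%d genes): %s\n", length(x$leading_edge),
              paste(head(x$leading_edge, 10), collapse = ", ")))
  invisible(x)
}

#' Tidy a preranked GSEA result
#' @param x A `magsig_gsea` object.
#' @param ... Unused.
#' @return One-row tibble with es, nes, p, n_perm, set and leading-edge
#'   sizes.
#' @export
tidy.magsig_gsea <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, p = x$p, n_perm = x$n_perm,
         set_size = length(x$gene_set),
         leading_edge_size = length(x$leading_edge),
         leading_edge = paste(x$leading_edge, collapse = ";"))
}

#' Glance at a preranked GSEA result
#' @inheritParams tidy.magsig_gsea
#' @return One-row tibble (es, nes, p, n_ranked, n_perm).
#' @export
glance.magsig_gsea <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, p = x$p, n_ranked = x$n_ranked,
         n_perm = x$n_perm)
}

#' Plot the GSEA running enrichment score
#'
#' Running enrichment score along the ranked list with a rug of set-hit
#' positions and the leading-edge region shaded.
#'
#' @param object A `magsig_gsea` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magsig_gsea <- function(object, ...) {
  run <- object$running
  le_end <- if (length(object$leading_edge) > 0) {
    max(run$position[run$feature %in% object$leading_edge])
  } else 0
  ggplot2::ggplot(run, ggplot2::aes(x = .data$position,
                                    y = .data$running_sum)) +
    { if (le_end > 0)
        ggplot2::annotate("rect", xmin = 0.5, xmax = le_end + 0.5,
                          ymin = -Inf, ymax = Inf, alpha = 0.08,
                          fill = "red") } +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = filter(run, .data$hit), sides = "b") +
    ggplot2::labs(x = "Rank in MAG-ordered list",
                  y = "Running enrichment score",
                  title = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                  object$es, object$nes, object$p)) +
    ggplot2::theme_minimal()
}
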