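# Interval conventions throughout: 0-based half-open [start, end);
# book-ended intervals ([a,b) and [b,c)) do not overlap and never merge.

iranges_of <- function(d) IRanges::IRanges(start = d$start + 1L,
                                           end = d$end)

#' Build consensus peaks from per-sample calls
#'
#' Merges intervals overlapping by at least 1 bp across samples into
#' maximal merged regions, counts the distinct samples contributing at
#' least one interval to each region, and keeps regions supported by at
#' least `min_support` samples.
#'
#' @param sample_peaks Tibble with columns chrom, start, end, sample_id.
#' @param min_support Minimum number of distinct supporting samples.
#' @return Tibble chrom / start / end / peak_id / support, sorted.
#' @export
#' @examples
#' pk <- tibble::tibble(chrom = "chr1",
#'                      start = c(100, 150, 300),
#'                      end = c(200, 250, 400),
#'                      sample_id = c("A", "B", "C"))
#' build_consensus_peaks(pk, min_support = 2)
build_consensus_peaks <- function(sample_peaks, min_support = 2) {
  if (nrow(sample_peaks) == 0) {
    warn("No input peaks; returning an empty consensus set.")
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), peak_id = character(),
                  support = integer()))
  }
  stopifnot(all(c("chrom", "start", "end", "sample_id")
                %in% names(sample_peaks)))
  if (any(sample_peaks$end <= sample_peaks$start)) {
    abort("All intervals must satisfy end > start.")
  }
  out <- sample_peaks |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- iranges_of(d)
      # min.gapwidth = 0 merges only true overlaps, never book-ended
      # intervals (half-open convention)
      merged <- IRanges::reduce(ir, min.gapwidth = 0L)
      hits <- IRanges::findOverlaps(ir, merged)
      support <- tapply(d$sample_id[S4Vectors_from(hits)],
                        S4Vectors_to(hits),
                        function(s) length(unique(s)))
      tibble(start = IRanges::start(merged) - 1L,
             end = IRanges::end(merged),
             support = as.integer(support[as.character(seq_along(merged))]))
    }) |>
    ungroup() |>
    filter(.data$support >= min_support) |>
    arrange(.data$chrom, .data$start)
  mutate(out, peak_id = sprintf("consensus_%04d", row_number()),
         .before = "support")
}

# thin wrappers so the S4Vectors generics resolve without attaching
S4Vectors_from <- function(h) S4Vectors::from(h)
S4Vectors_to <- function(h) S4Vectors::to(h)

#' Annotate peaks with their nearest TSS
#'
#' Assigns each peak to the gene whose TSS is closest to the peak
#' centre (`floor((start + end) / 2)`), breaking ties toward the
#' lexicographically smaller gene id. The signed distance is
#' `(centre - TSS) x strand_sign` (positive = downstream of the TSS);
#' peaks within `promoter_window` of the TSS are flagged as promoter
#' peaks. Peaks on chromosomes absent from the TSS table are returned
#' unannotated (NA gene).
#'
#' @param peaks Tibble chrom / start / end (plus any id columns).
#' @param tss TSS tibble: gene, chrom, pos (0-based), strand.
#' @param promoter_window Promoter distance cutoff in bp.
#' @return `peaks` with gene, distance, promoter, annotated columns.
#' @export
annotate_nearest_tss <- function(peaks, tss, promoter_window = 2000) {
  if (nrow(tss) == 0) abort("TSS table is empty.")
  tss <- arrange(as_tibble(tss), .data$gene)
  res <- purrr::pmap_dfr(
    peaks[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      centre <- floor((start + end) / 2)
      cand <- tss[tss$chrom == chrom, ]
      if (nrow(cand) == 0) {
        return(tibble(gene = NA_character_, distance = NA_real_,
                      promoter = NA, annotated = FALSE))
      }
      dd <- abs(centre - cand$pos)
      best <- which(dd == min(dd))[1]  # tss sorted by gene id: tie -> smaller id
      sgn <- if (cand$strand[best] == "+") 1 else -1
      dist <- (centre - cand$pos[best]) * sgn
      tibble(gene = cand$gene[best], distance = dist,
             promoter = abs(dist) <= promoter_window, annotated = TRUE)
    })
  bind_cols(as_tibble(peaks), res)
}

#' Filter footprints by purity
#'
#' Keeps footprint calls whose positive-predictive-value style purity
#' score strictly exceeds `min_purity` (default 0.9).
#'
#' @param calls Footprint tibble with a `purity` column.
#' @param min_purity Strict lower bound.
#' @return Filtered tibble.
#' @export
footprint_filter <- function(calls, min_purity = 0.9) {
  stopifnot("purity" %in% names(calls))
  filter(as_tibble(calls), .data$purity > min_purity)
}

#' Per-group TF footprint proportions
#'
#' Normalises footprint counts per TF by the total number of footprints
#' detected in each group, so shares within a group sum to one. Empty
#' groups are excluded with a warning.
#'
#' @param calls Footprint tibble with `group` and `tf` columns.
#' @return Tibble group / tf / count / share.
#' @export
footprint_proportions <- function(calls) {
  stopifnot(all(c("group", "tf") %in% names(calls)))
  if (nrow(calls) == 0) {
    warn("No footprint calls; returning an empty table.")
    return(tibble(group = character(), tf = character(),
                  count = integer(), share = double()))
  }
  calls |>
    count(.data$group, .data$tf, name = "count") |>
    group_by(.data$group) |>
    mutate(share = .data$count / sum(.data$count)) |>
    ungroup()
}

# peaks that contain >= 1 footprint of each TF (binary containment)
peaks_with_tf <- function(calls, peaks) {
  if (nrow(calls) == 0 || nrow(peaks) == 0) {
    return(tibble(tf = character(), peak_id = character()))
  }
  purrr::map_dfr(split(calls, calls$chrom), function(d) {
    pk <- peaks[peaks$chrom == d$chrom[1], ]
    if (nrow(pk) == 0) return(NULL)
    hits <- IRanges::findOverlaps(iranges_of(d), iranges_of(pk))
    tibble(tf = d$tf[S4Vectors_from(hits)],
           peak_id = pk$peak_id[S4Vectors_to(hits)])
  }) |> distinct()
}

#' TF footprint enrichment in opening/closing peaks
#'
#' For each TF and each direction, counts the foreground peaks
#' (opening or closing) containing at least one footprint of the TF and
#' tests them against the age-stable background peaks with an
#' upper-tail hypergeometric test: N = foreground + background peaks,
#' K = peaks containing the TF anywhere, n = foreground peaks,
#' k = foreground peaks containing the TF. This is a deliberately
#' bias-naive replacement for read-level bias-corrected footprint
#' enrichment; q-values are BH per direction (within each stratum when
#' a `stratum` column is present), and a TF is reported pan-stratum
#' when q < 0.05 in at least `min_strata` strata.
#'
#' @param calls Footprint tibble (chrom/start/end/tf, optional
#'   `stratum`).
#' @param opening_peaks,closing_peaks,background_peaks Peak tibbles
#'   (chrom/start/end/peak_id), pairwise disjoint.
#' @param min_strata Pan-stratum support rule.
#' @return Tibble: stratum, direction, tf, k, K, n, N, p, q, enriched,
#'   plus a `pan_stratum` summary attribute column `support` via
#'   [shared_tf_sets()] if desired.
#' @export
footprint_peak_enrichment <- function(calls, opening_peaks,
                                      closing_peaks, background_peaks,
                                      min_strata = 2) {
  if (nrow(background_peaks) == 0) {
    abort("Background peak set is empty; enrichment is undefined.")
  }
  if (!"stratum" %in% names(calls)) calls$stratum <- "all"
  directions <- list(opening = opening_peaks, closing = closing_peaks)
  out <- purrr::map_dfr(split(as_tibble(calls), calls$stratum),
                        function(d) {
    purrr::imap_dfr(directions, function(fg, dir_name) {
      if (nrow(fg) == 0) return(NULL)
      all_peaks <- bind_rows(fg, background_peaks)
      hits <- peaks_with_tf(d, all_peaks)
      N <- nrow(all_peaks)
      n <- nrow(fg)
      tfs <- sort(unique(d$tf))
      rows <- purrr::map_dfr(tfs, function(tf) {
        hp <- hits$peak_id[hits$tf == tf]
        K <- length(hp)
        k <- length(intersect(hp, fg$peak_id))
        p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE)
        tibble(stratum = d$stratum[1], direction = dir_name, tf = tf,
               k = k, K = K, n = n, N = N, p = p)
      })
      rows$q <- bh_adjust(rows$p)
      rows$enriched <- rows$q < 0.05
      rows
    })
  })
  support <- out |>
    group_by(.data$direction, .data$tf) |>
    summarise(pan_stratum_support = sum(.data$enriched),
              .groups = "drop")
  out <- left_join(out, support, by = c("direction", "tf")) |>
    mutate(pan_stratum = .data$pan_stratum_support >= min_strata)
  out
}

#' Cross-stratum shared TF sets (upset counts)
#'
#' Given per-stratum sets of enriched TFs, counts the TFs enriched in
#' exactly each nonempty combination of strata, plus the shared-by-all
#' count.
#'
#' @param enriched_sets Named list of character vectors (one per
#'   stratum).
#' @return List with `combinations` (tibble combination / count /
#'   members) and `shared_all` (integer).
#' @export
shared_tf_sets <- function(enriched_sets) {
  stopifnot(length(enriched_sets) >= 1)
  strata <- names(enriched_sets)
  all_tfs <- sort(unique(unlist(enriched_sets)))
  member <- vapply(enriched_sets, function(s) all_tfs %in% s,
                   logical(length(all_tfs)))
  if (length(all_tfs) == 1) member <- matrix(member, nrow = 1)
  combo <- apply(member, 1, function(row)
    paste(strata[row], collapse = "&"))
  tb <- tibble(tf = all_tfs, combination = combo) |>
    group_by(.data$combination) |>
    summarise(count = n(),
              members = paste(sort(.data$tf), collapse = ";"),
              .groups = "drop")
  shared_all <- sum(combo == paste(strata, collapse = "&"))
  list(combinations = tb, shared_all = shared_all)
}

#' Footprint counts in a locus window around a gene's TSS
#'
#' Counts footprints overlapping the window
#' `[TSS - window, TSS + window)` per TF and group.
#'
#' @param calls Footprint tibble (chrom/start/end/tf/group).
#' @param gene Gene id (must be present in `tss`).
#' @param tss TSS tibble.
#' @param window Half-window in bp (default 100 kb each side).
#' @return Tibble tf / group / count.
#' @export
locus_footprint_counts <- function(calls, gene, tss, window = 1e5) {
  row <- tss[tss$gene == gene, ]
  if (nrow(row) == 0) abort(sprintf("Gene '%s' not in the TSS table.", gene))
  lo <- row$pos - window
  hi <- row$pos + window
  hits <- filter(as_tibble(calls),
                 .data$chrom == row$chrom,
                 .data$start < hi, .data$end > lo)
  count(hits, .data$tf, .data$group, name = "count")
}

#' Aggregate cut-site profile around footprint centres
#'
#' Averages per-base cut counts at offsets `-flank..+flank` around the
#' given centres, then divides by the total cut count of the group
#' (library-size normalisation). Positions absent from the sparse
#' signal carry zero counts. Centres closer than `flank` to a
#' chromosome edge are skipped and counted.
#'
#' @param cut_signal Tibble pos / count (one group's signal; positions
#'   not listed are zero).
#' @param footprint_centers Integer vector of centre positions.
#' @param flank Half-width of the profile in bp.
#' @param chrom_length Chromosome length (for edge checks); `Inf`
#'   disables the upper check.
#' @return List with `profile` (tibble offset / mean_normalized_cuts)
#'   and `n_skipped`.
#' @export
aggregate_cut_profile <- function(cut_signal, footprint_centers,
                                  flank = 100, chrom_length = Inf) {
  usable <- footprint_centers[footprint_centers >= flank &
                                footprint_centers + flank < chrom_length]
  n_skipped <- length(footprint_centers) - length(usable)
  if (length(usable) == 0) {
    abort("No usable footprint centres (all within `flank` of an edge).")
  }
  total <- sum(cut_signal$count)
  if (total <= 0) abort("Cut signal has zero total counts.")
  offsets <- -flank:flank
  look <- setNames(cut_signal$count, cut_signal$pos)
  prof <- vapply(offsets, function(d) {
    v <- look[as.character(usable + d)]
    sum(v, na.rm = TRUE) / length(usable)
  }, numeric(1))
  list(profile = tibble(offset = offsets,
                        mean_normalized_cuts = prof / total),
       n_skipped = n_skipped)
}

#' Plot aggregate cut-site profiles
#'
#' @param profiles Tibble with columns offset, mean_normalized_cuts and
#'   optionally group.
#' @return A ggplot of the average accessibility profile(s).
#' @export
plot_cut_profile <- function(profiles) {
  aes <- if ("group" %in% names(profiles)) {
    ggplot2::aes(x = .data$offset, y = .data$mean_normalized_cuts,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$offset, y = .data$mean_normalized_cuts)
  }
  ggplot2::ggplot(profiles, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from footprint centre (bp)",
                  y = "Mean normalised cut count") +
    ggplot2::theme_minimal()
}
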