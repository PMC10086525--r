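#' Hypergeometric over-representation of gene-set modules
#'
#' For each module in the collection, tests whether the query set
#' over-represents the module within the universe: with universe size
#' N, module size K (after intersecting with the universe), query size
#' n and overlap k, the p-value is the exact upper tail
#' \eqn{P(X \ge k)} of the hypergeometric(N, K, n) distribution.
#' P-values are BH-adjusted across the collection; modules with
#' fdr < 0.05 are flagged enriched. Percent overlap is 100 k / K.
#'
#' @param query Character vector (must be a subset of `universe`).
#' @param collection Gene-set tibble from [read_gmt()] (columns `set`,
#'   `members` list-column), or a named list of character vectors.
#' @param universe Character vector defining the background (typically
#'   the expressed genes of the stratum).
#' @param fdr_max Enrichment flag threshold.
#' @return Tibble: set, k, K, n, N, percent_overlap, p, fdr, enriched.
#' @export
#' @examples
#' hypergeom_enrich(query = letters[1:5],
#'                  collection = list(mod = letters[3:9]),
#'                  universe = letters)
hypergeom_enrich <- function(query, collection, universe,
                             fdr_max = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(universe) == 0) abort("Universe is empty.")
  if (length(query) == 0) abort("Query set is empty.")
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    abort(sprintf("Query contains genes outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  if (is.data.frame(collection)) {
    sets <- setNames(collection$members, collection$set)
  } else {
    sets <- collection
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap(sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n,
                                   lower.tail = FALSE)
    tibble(set = nm, k = k, K = K, n = n, N = N,
           percent_overlap = if (K > 0) 100 * k / K else 0, p = p)
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(out$p)
  out$enriched <- out$fdr < fdr_max
  out
}

#' Overlap test between two gene sets
#'
#' Upper-tail hypergeometric test of the overlap between sets A and B
#' within a universe (query = A, module = B).
#'
#' @param setA,setB Character vectors, subsets of `universe`.
#' @param universe Background gene set.
#' @return One-row enrichment tibble (as [hypergeom_enrich()]).
#' @export
overlap_test <- function(setA, setB, universe) {
  stray <- setdiff(unique(c(setA, setB)), universe)
  if (length(stray) > 0) {
    abort(sprintf("Sets contain genes outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  hypergeom_enrich(setA, list(setB = setB), universe)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by enumeration of rank assignments when the smaller sample
#' has at most `exact_max_n` observations and the pooled data are
#' tie-free; otherwise the continuity-corrected normal approximation
#' with the tie-adjusted variance (midranks for ties).
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact_max_n Largest min(n_x, n_y) for the exact mode.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 10) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max_n
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  unname(res$p.value)
}
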