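make_assoc <- function(p, log2fc, genes = paste0("g", seq_along(p))) {
  tibble::tibble(feature = genes, p = p, log2fc_span = log2fc)
}

test_that("stratum ranking orders by p with the documented tie-breaks", {
  r <- rank_stratum(make_assoc(c(0.001, 0.01, 0.0005), c(1, 1, 1),
                               c("a", "b", "c")))
  expect_equal(r$rank[match(c("a", "b", "c"), r$feature)], c(2, 3, 1))
  tie <- rank_stratum(make_assoc(c(0.01, 0.01), c(0.5, 2.0),
                                 c("g1", "g2")))
  expect_equal(tie$feature[tie$rank == 1], "g2")
  full_tie <- rank_stratum(make_assoc(c(0.5, 0.5), c(1, 1),
                                      c("zz", "aa")))
  expect_equal(full_tie$feature[full_tie$rank == 1], "aa")
  expect_error(rank_stratum(make_assoc(c(0.1, 0.2), c(1, 1),
                                       c("a", "a"))), "Duplicate")
})

test_that("MAG hand-worked values and missing-stratum handling are exact", {
  # gene ranked 1 everywhere: m = 1 per tissue, M = number of tissues
  ranks <- tidyr::expand_grid(strain = c("s1", "s2"),
                              tissue = paste0("t", 1:4)) |>
    dplyr::mutate(feature = "star", rank = 1, n_tested = 10,
                  direction = 1)
  other <- dplyr::mutate(ranks, feature = "dull", rank = 5)
  mg <- mag_scores(dplyr::bind_rows(ranks, other))
  expect_equal(mg$mag[mg$feature == "star"], 4.0)
  expect_equal(mg$final_rank[mg$feature == "star"], 1L)
  # ranks (2, 8) across two strains: geometric mean of inverses = 1/4
  two <- tibble::tibble(feature = "g", strain = c("A", "B"),
                        tissue = "t1", rank = c(2, 8), n_tested = 50,
                        direction = c(1, 1))
  pad <- tibble::tibble(feature = "h", strain = c("A", "B"),
                        tissue = "t1", rank = c(1, 1), n_tested = 50,
                        direction = c(1, -1))
  m2 <- mag_scores(dplyr::bind_rows(two, pad))
  expect_equal(m2$m_t1[m2$feature == "g"], 0.25)
  expect_equal(m2$consensus_direction[m2$feature == "h"], "mixed")
  # summation across tissues
  expect_equal(sum(c(1.0, 0.5, 0.25, 0.125)), 1.875)
  expect_error(mag_scores(two, strains = c("A", "B"),
                          tissues = c("t1", "t2")), "t2")
})

test_that("MAG equals the brute-force formula and is order-invariant", {
  set.seed(42)
  strains <- c("B6", "NZO")
  tissues <- c("PBL", "spleen", "naiveCD8", "memoryCD8")
  for (i in 1:5) {
    G <- sample(20:60, 1)
    genes <- sprintf("g%03d", seq_len(G))
    ranks <- tidyr::expand_grid(strain = strains, tissue = tissues) |>
      purrr::pmap_dfr(function(strain, tissue) {
        tibble::tibble(feature = genes, strain = strain,
                       tissue = tissue, rank = sample(G),
                       n_tested = G, direction = 1)
      })
    mg <- mag_scores(ranks)
    br <- oracle_mag(as.data.frame(ranks), strains, tissues)
    expect_equal(mg$mag, unname(br[mg$feature]), tolerance = 1e-12)
    # invariance to strain and tissue relabelling of table order
    shuf <- ranks[sample(nrow(ranks)), ]
    expect_equal(dplyr::arrange(mag_scores(shuf), feature)$mag,
                 dplyr::arrange(mg, feature)$mag, tolerance = 1e-14)
  }
})

test_that("improving any single rank never decreases the MAG score", {
  set.seed(7)
  strains <- c("A", "B")
  tissues <- c("t1", "t2")
  G <- 15
  genes <- sprintf("g%02d", 1:G)
  base <- tidyr::expand_grid(strain = strains, tissue = tissues) |>
    purrr::pmap_dfr(function(strain, tissue) {
      tibble::tibble(feature = genes, strain = strain, tissue = tissue,
                     rank = sample(G), n_tested = G, direction = 1)
    })
  g0 <- "g05"
  m0 <- mag_scores(base)$mag[mag_scores(base)$feature == g0]
  for (j in which(base$feature == g0)) {
    better <- base
    old <- better$rank[j]
    if (old == 1) next
    # swap toward rank 1 within the stratum
    k <- which(better$feature != g0 & better$strain == better$strain[j] &
                 better$tissue == better$tissue[j] & better$rank == 1)
    better$rank[k] <- old
    better$rank[j] <- 1
    m1 <- mag_scores(better)$mag[mag_scores(better)$feature == g0]
    expect_gte(m1, m0)
  }
})

test_that("genes absent from a stratum receive the worst-plus-one rank", {
  present <- tibble::tibble(feature = c("a", "b"), strain = "A",
                            tissue = "t", rank = c(1, 2), n_tested = 2,
                            direction = 1)
  partial <- tibble::tibble(feature = "a", strain = "B", tissue = "t",
                            rank = 1, n_tested = 1, direction = 1)
  mg <- mag_scores(dplyr::bind_rows(present, partial))
  # b missing in strain B -> rank n_tested + 1 = 2 there
  expect_equal(mg$m_t[mg$feature == "b"], sqrt((1 / 2) * (1 / 2)))
  dropped <- mag_scores(dplyr::bind_rows(present, partial),
                        absent_rank = "drop")
  expect_equal(dropped$feature, "a")
})

test_that("GSEA reproduces enumeration oracles at small N", {
  # N = 3, set = top gene, unweighted
  g <- preranked_gsea(tibble::tibble(feature = c("x", "y", "z"),
                                     mag = c(3, 2, 1)), "x",
                      weight_exponent = 0, exhaustive = TRUE)
  expect_equal(g$es, 1.0)
  # N = 4 worked example: ES 1.0, NES 1.6, p = 2/7
  m4 <- tibble::tibble(feature = c("a", "b", "c", "d"), mag = 4:1)
  g4 <- preranked_gsea(m4, c("a", "b"), weight_exponent = 0,
                       exhaustive = TRUE)
  expect_equal(g4$es, 1.0)
  expect_equal(g4$nes, 1.6)
  expect_equal(g4$p, 2 / 7)
  expect_equal(g4$leading_edge, c("a", "b"))
  # bottom-placed set: non-positive branch
  g5 <- preranked_gsea(tibble::tibble(feature = letters[1:5], mag = 5:1),
                       c("d", "e"), weight_exponent = 0,
                       exhaustive = TRUE)
  expect_equal(g5$es, 0)
  expect_gte(g5$p, 0.5)
  expect_equal(g5$leading_edge, character(0))
  # weighted exhaustive agrees with the independent walker
  set.seed(3)
  for (i in 1:10) {
    N <- sample(5:8, 1)
    k <- sample(2:3, 1)
    scores <- sort(abs(rnorm(N, sd = 2)), decreasing = TRUE)
    mag <- tibble::tibble(feature = sprintf("f%02d", 1:N), mag = scores)
    members <- sample(mag$feature, k)
    got <- preranked_gsea(mag, members, weight_exponent = 1,
                          exhaustive = TRUE)
    want <- oracle_gsea_exhaustive(scores, mag$feature %in% members)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$nes, want$nes, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo GSEA p converges to the exhaustive p", {
  set.seed(11)
  for (i in 1:5) {
    N <- sample(6:8, 1)
    k <- 2
    mag <- tibble::tibble(feature = sprintf("f%02d", 1:N),
                          mag = sort(runif(N, 0.1, 3), decreasing = TRUE))
    members <- sample(mag$feature, k)
    want <- oracle_gsea_exhaustive(mag$mag, mag$feature %in% members)
    mc <- preranked_gsea(mag, members, weight_exponent = 1,
                         n_perm = 4000, seed = i)
    # the Monte-Carlo estimand is the enumeration tail probability;
    # the add-one rule shifts p by at most 1/(n_perm + 1) each way
    se <- sqrt(want$tail * (1 - want$tail) / 4000)
    expect_lt(abs(mc$p - want$tail), 3 * se + 2 / 4000)
  }
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  set.seed(14)
  for (i in 1:5) {
    N <- 200
    mag <- tibble::tibble(feature = sprintf("g%03d", 1:N),
                          mag = sort(rexp(N), decreasing = TRUE))
    members <- sample(mag$feature[1:40], 8)
    ours <- preranked_gsea(mag, members, weight_exponent = 1,
                           n_perm = 100, seed = i)
    ref <- fgsea::calcGseaStat(
      stats::setNames(mag$mag, mag$feature),
      selectedStats = which(mag$feature %in% members), gseaParam = 1)
    # same running-sum statistic when enrichment is at the top
    expect_equal(ours$es, ref, tolerance = 1e-12)
  }
})

test_that("GSEA input validation rejects degenerate sets", {
  mag <- tibble::tibble(feature = c("a", "b"), mag = c(2, 1))
  expect_error(preranked_gsea(mag, "zz"), "empty intersection")
  expect_error(preranked_gsea(mag, c("a", "b")), "whole")
})
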