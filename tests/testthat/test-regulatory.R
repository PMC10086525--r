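stratum_label <- magsig:::stratum_label

test_that("consensus peaks follow the worked merge example", {
  pk <- tibble::tibble(chrom = "chr1",
                       start = c(100, 150, 300),
                       end = c(200, 250, 400),
                       sample_id = c("A", "B", "C"))
  out <- build_consensus_peaks(pk, min_support = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$end, 250)
  expect_equal(out$support, 2L)
  # identical peak in three samples
  trip <- tibble::tibble(chrom = "chr1", start = 10, end = 50,
                         sample_id = c("A", "B", "C"))
  out3 <- build_consensus_peaks(trip, min_support = 2)
  expect_equal(out3$support, 3L)
  # book-ended intervals do not merge under half-open semantics
  be <- tibble::tibble(chrom = "chr1", start = c(100, 200),
                       end = c(200, 300), sample_id = c("A", "B"))
  expect_equal(nrow(build_consensus_peaks(be, min_support = 2)), 0)
  expect_equal(nrow(build_consensus_peaks(be, min_support = 1)), 2)
})

test_that("consensus merging matches brute force on random draws", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    df <- tibble::tibble(
      chrom = "c",
      start = sample(0:60, n, replace = TRUE),
      sample_id = sample(LETTERS[1:4], n, replace = TRUE))
    df$end <- df$start + sample(1:15, n, replace = TRUE)
    ms <- sample(1:3, 1)
    got <- build_consensus_peaks(df, min_support = ms)
    want <- oracle_consensus(as.data.frame(df), ms)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$support, want$support)
    }
  }
  # order invariance
  df <- tibble::tibble(chrom = "c", start = c(5, 1, 8, 3),
                       end = c(12, 6, 20, 9),
                       sample_id = c("A", "B", "A", "C"))
  a <- build_consensus_peaks(df, 2)
  b <- build_consensus_peaks(df[sample(4), ], 2)
  expect_equal(a, b)
})

test_that("nearest-TSS annotation applies distance and strand conventions", {
  tss <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                        pos = c(1000L, 5000L), strand = c("+", "+"))
  pk <- tibble::tibble(chrom = "chr1", start = 1400, end = 1600)
  ann <- annotate_nearest_tss(pk, tss)
  expect_equal(ann$gene, "g1")
  expect_equal(ann$distance, 500)
  expect_true(ann$promoter)
  # minus strand flips the sign (upstream)
  tss_m <- dplyr::mutate(tss, strand = c("-", "+"))
  ann_m <- annotate_nearest_tss(pk, tss_m)
  expect_equal(ann_m$distance, -500)
  # peak centred on the TSS
  on <- annotate_nearest_tss(
    tibble::tibble(chrom = "chr1", start = 900, end = 1100), tss)
  expect_equal(on$distance, 0)
  expect_true(on$promoter)
  # missing chromosome -> unannotated
  off <- annotate_nearest_tss(
    tibble::tibble(chrom = "chrX", start = 0, end = 10), tss)
  expect_false(off$annotated)
  expect_true(is.na(off$gene))
})

test_that("nearest-TSS matches an all-pairs scan on random sets", {
  set.seed(21)
  for (i in 1:40) {
    tss <- tibble::tibble(
      gene = sprintf("g%02d", 1:6), chrom = "c",
      pos = sample(0:5000, 6),
      strand = sample(c("+", "-"), 6, replace = TRUE))
    pk <- tibble::tibble(chrom = "c", start = sample(0:4900, 4))
    pk$end <- pk$start + sample(50:200, 4)
    ann <- annotate_nearest_tss(pk, tss, promoter_window = 500)
    for (j in seq_len(nrow(pk))) {
      centre <- floor((pk$start[j] + pk$end[j]) / 2)
      want <- oracle_nearest_tss(centre, "c", as.data.frame(tss))
      expect_equal(ann$gene[j], want$gene)
      expect_equal(ann$distance[j], want$distance)
      expect_equal(ann$promoter[j], abs(want$distance) <= 500)
    }
  }
})

test_that("purity filtering is strict at the threshold", {
  calls <- tibble::tibble(tf = "Jun", chrom = "c", start = 1:3,
                          end = 2:4, purity = c(0.95, 0.90, 0.85))
  expect_equal(nrow(footprint_filter(calls)), 1)
  expect_equal(nrow(footprint_filter(calls[0, ])), 0)
  expect_equal(footprint_filter(calls, min_purity = 0),
               calls)
})

test_that("footprint proportions are row-stochastic", {
  calls <- tibble::tibble(group = c(rep("g1", 100), rep("g2", 10)),
                          tf = c(rep("A", 30), rep("B", 70),
                                 rep("A", 10)))
  pr <- footprint_proportions(calls)
  expect_equal(pr$share[pr$group == "g1" & pr$tf == "A"], 0.3)
  expect_equal(pr$share[pr$group == "g1" & pr$tf == "B"], 0.7)
  expect_equal(pr$share[pr$group == "g2"], 1.0)
  sums <- tapply(pr$share, pr$group, sum)
  expect_equal(as.numeric(sums), rep(1, 2))
})

test_that("footprint enrichment matches the exact tail oracle", {
  # construct 100 fg / 1000 bg peaks, TF hits 20 fg and 50 bg
  fg <- tibble::tibble(chrom = "c",
                       start = seq(0, by = 1000, length.out = 100))
  fg$end <- fg$start + 500
  fg$peak_id <- sprintf("fg%03d", 1:100)
  bg <- tibble::tibble(chrom = "c",
                       start = seq(2e5, by = 1000, length.out = 1000))
  bg$end <- bg$start + 500
  bg$peak_id <- sprintf("bg%04d", 1:1000)
  hit_peaks <- dplyr::bind_rows(fg[1:20, ], bg[1:50, ])
  calls <- tibble::tibble(tf = "TF1", chrom = "c",
                          start = hit_peaks$start + 10,
                          end = hit_peaks$start + 30)
  enr <- footprint_peak_enrichment(calls, opening_peaks = fg,
                                   closing_peaks = fg[0, ],
                                   background_peaks = bg)
  expect_equal(enr$k, 20)
  expect_equal(enr$K, 70)
  expect_equal(enr$p, oracle_hyper_tail(20, 70, 1100, 100),
               tolerance = 1e-12)
  # TF present in every peak: p = 1
  all_calls <- tibble::tibble(tf = "TF2", chrom = "c",
                              start = c(fg$start, bg$start) + 1,
                              end = c(fg$start, bg$start) + 5)
  enr_all <- footprint_peak_enrichment(all_calls, fg, fg[0, ], bg)
  expect_equal(enr_all$p, 1)
  expect_error(footprint_peak_enrichment(calls, fg, fg[0, ], bg[0, ]),
               "Background")
})

test_that("shared TF sets count exact combinations", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z"), C = "z")
  out <- shared_tf_sets(sets)
  cmb <- out$combinations
  expect_equal(out$shared_all, 1)
  expect_equal(cmb$count[cmb$combination == "A"], 1)
  expect_equal(cmb$count[cmb$combination == "A&B"], 1)
  expect_equal(cmb$count[cmb$combination == "A&B&C"], 1)
  ident <- shared_tf_sets(list(A = c("p", "q"), B = c("p", "q")))
  expect_equal(ident$shared_all, 2)
  disj <- shared_tf_sets(list(A = "p", B = "q"))
  expect_equal(disj$shared_all, 0)
})

test_that("locus window counts apply the overlap rule", {
  tss <- tibble::tibble(gene = "Il6", chrom = "c", pos = 500000L,
                        strand = "+")
  calls <- tibble::tibble(
    tf = "Jun", group = "old",
    chrom = "c",
    start = c(450000, 399990, 280000, 599999),
    end = c(450020, 400010, 280020, 600019))
  out <- locus_footprint_counts(calls, "Il6", tss, window = 1e5)
  # inside, straddling the lower edge, outside, straddling the upper edge
  expect_equal(out$count, 3)
  expect_error(locus_footprint_counts(calls, "nope", tss), "nope")
})

test_that("aggregate cut profiles normalise and localise correctly", {
  # unit impulse at every centre
  centers <- c(500L, 1500L, 2500L)
  sig <- tibble::tibble(pos = centers, count = 1L)
  prof <- aggregate_cut_profile(sig, centers, flank = 10)
  expect_equal(prof$profile$mean_normalized_cuts[prof$profile$offset == 0],
               1 / 3)
  expect_equal(sum(prof$profile$mean_normalized_cuts), 1 / 3)
  # constant signal gives a flat profile; doubling leaves it unchanged
  allpos <- tibble::tibble(pos = 0:3000, count = 2L)
  p1 <- aggregate_cut_profile(allpos, centers, flank = 5)
  expect_true(all(abs(diff(p1$profile$mean_normalized_cuts)) < 1e-15))
  doubled <- dplyr::mutate(allpos, count = count * 2L)
  p2 <- aggregate_cut_profile(doubled, centers, flank = 5)
  expect_equal(p1$profile$mean_normalized_cuts,
               p2$profile$mean_normalized_cuts)
  # edge centres are skipped and counted
  p3 <- aggregate_cut_profile(allpos, c(2L, centers), flank = 10)
  expect_equal(p3$n_skipped, 1)
  expect_error(aggregate_cut_profile(allpos, 2L, flank = 10), "usable")
})

test_that("synthetic aging TFs are recovered as enriched in opening peaks", {
  cfg <- sim_config(seed = 31, n_genes = 10)
  reg <- generate_regulatory(cfg)
  fps <- footprint_filter(reg$footprints) |>
    dplyr::mutate(stratum = stratum_label(strain, tissue))
  old <- dplyr::filter(fps, age_group == "old")
  pk <- reg$peaks
  enr <- footprint_peak_enrichment(
    old,
    opening_peaks = dplyr::filter(pk, class == "opening"),
    closing_peaks = dplyr::filter(pk, class == "closing"),
    background_peaks = dplyr::filter(pk, class == "stable"))
  aging <- dplyr::filter(enr, direction == "opening",
                         tf %in% reg$truth$aging_tfs)
  expect_true(all(aging$pan_stratum))
})
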