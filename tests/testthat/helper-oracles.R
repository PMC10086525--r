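# Independent brute-force oracles used to check the package's
# implementations. These deliberately re-derive each quantity from its
# definition with naive loops, sharing no code with the package.

# MAG: geometric mean of inverse ranks over strains per tissue, summed
# over tissues. `ranks` is a long data frame feature/strain/tissue/rank.
oracle_mag <- function(ranks, strains, tissues) {
  genes <- unique(ranks$feature)
  # direct lookup table gene x (strain, tissue) of ranks
  key <- paste(ranks$strain, ranks$tissue)
  lut <- matrix(NA_real_, length(genes),
                length(strains) * length(tissues),
                dimnames = list(genes, as.vector(outer(
                  strains, tissues, paste))))
  lut[cbind(match(ranks$feature, genes), match(key, colnames(lut)))] <-
    ranks$rank
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in seq_along(genes)) {
    total <- 0
    for (t in tissues) {
      prod_inv <- 1
      for (s in strains) {
        prod_inv <- prod_inv * (1 / lut[g, paste(s, t)])
      }
      total <- total + prod_inv^(1 / length(strains))
    }
    out[g] <- total
  }
  out
}

# GSEA ES by walking the full list step by step for one hit placement.
oracle_gsea_es <- function(hit_positions, weights_at_hits, N) {
  k <- length(hit_positions)
  run <- 0
  best <- 0
  wsum <- sum(weights_at_hits)
  for (i in seq_len(N)) {
    j <- match(i, hit_positions)
    if (!is.na(j)) {
      run <- run + weights_at_hits[j] / wsum
    } else {
      run <- run - 1 / (N - k)
    }
    if (run > best) best <- run
  }
  best
}

# Exhaustive GSEA null over all placements; add-one p and NES.
oracle_gsea_exhaustive <- function(scores, hits) {
  N <- length(scores)
  k <- sum(hits)
  obs <- oracle_gsea_es(which(hits), scores[which(hits)], N)
  placements <- utils::combn(N, k)
  null_es <- apply(placements, 2, function(pp)
    oracle_gsea_es(pp, scores[pp], N))
  # tie tolerance mirrors the documented convention: placements whose
  # ES is mathematically equal to the observed one count as >=
  p <- (1 + sum(null_es >= obs - 1e-12)) / (1 + ncol(placements))
  pos <- null_es[null_es > 1e-12]
  list(es = obs, p = p, tail = mean(null_es >= obs - 1e-12),
       nes = if (length(pos)) obs / mean(pos) else NA_real_)
}

# Hypergeometric upper tail P(X >= k) from the counting definition.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Textbook BH step-up with a running minimum.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Closed-form simple linear regression slope/se/p.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, se = se, p = p)
}

# Interval merging by repeated all-pairs sweeps (0-based half-open;
# strictly-overlapping intervals only), with distinct-sample support.
oracle_consensus <- function(df, min_support) {
  regions <- lapply(seq_len(nrow(df)), function(i)
    list(start = df$start[i], end = df$end[i],
         samples = df$sample_id[i]))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i >= j) next
        a <- regions[[i]]; b <- regions[[j]]
        if (a$start < b$end && b$start < a$end) {
          regions[[i]] <- list(start = min(a$start, b$start),
                               end = max(a$end, b$end),
                               samples = union(a$samples, b$samples))
          regions[[j]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  keep <- Filter(function(r) length(r$samples) >= min_support, regions)
  if (length(keep) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      support = integer()))
  }
  out <- data.frame(start = sapply(keep, `[[`, "start"),
                    end = sapply(keep, `[[`, "end"),
                    support = sapply(keep, function(r) length(r$samples)))
  out[order(out$start), , drop = FALSE]
}

# Nearest TSS by scanning every entry; ties toward smaller gene id.
oracle_nearest_tss <- function(centre, chrom, tss) {
  cand <- tss[tss$chrom == chrom, ]
  if (nrow(cand) == 0) return(NULL)
  d <- abs(centre - cand$pos)
  best <- cand[d == min(d), ]
  best <- best[order(best$gene), ][1, ]
  sgn <- if (best$strand == "+") 1 else -1
  list(gene = best$gene, distance = (centre - best$pos) * sgn)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration (no ties).
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  W <- colSums(matrix(r[idx], nrow = nx))
  w_obs <- sum(r[seq_len(nx)])
  p_le <- mean(W <= w_obs)
  p_ge <- mean(W >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Tiny deterministic study fixture shared across tests.
tiny_study <- function(seed = 11, n_genes = 300, reps = 3) {
  generate_study(sim_config(
    seed = seed, n_genes = n_genes, replicates_per_age = reps,
    dispersion = 0.1))
}
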