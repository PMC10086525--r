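#' Synthetic study configuration
#'
#' Builds the configuration object used by all synthetic-data generators.
#' The defaults emulate a two-strain (B6, NZO) design across four immune
#' tissues/cell types (PBL, spleen, naive and memory CD8 T cells), with
#' young (3 months) and old (18 months) animals, negative-binomial counts,
#' a small set of planted conserved aging genes and per-strain specific
#' genes, plus synthetic peaks, footprints, cut-site signal and cell
#' composition percentages.
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param strains Character vector of strain labels.
#' @param tissues Character vector of tissue/cell-type labels.
#' @param strata Data frame with columns `strain`, `tissue`; defaults to
#'   the full strain x tissue cross.
#' @param ages_months Numeric vector of study ages in months.
#' @param replicates_per_age Animals per (stratum, age); must be >= 2.
#' @param n_genes Number of genes simulated.
#' @param planted_conserved List with `genes` (character) and `log2fc`
#'   (numeric scalar or per-gene vector): effect over the min-to-max age
#'   span, applied in every stratum.
#' @param planted_strain_specific Named list (by strain) of lists with
#'   `genes` and `log2fc`; effect applied only in that strain's strata.
#' @param dispersion Per-gene NB dispersion: a scalar, a length-`n_genes`
#'   vector, or `NULL` to draw from gamma(shape 2, mean 0.1).
#' @param library_size_range Length-2 positive integer range for library
#'   sizes (uniform draw per sample).
#' @param baseline_log2_mean_range Length-2 range for per-gene baseline
#'   log2 relative abundance (counts mean = library size x 2^baseline).
#' @param regulatory List of regulatory-landscape parameters; see
#'   [generate_regulatory()].
#' @param composition List of cell-composition parameters; see
#'   [generate_composition()].
#' @param variance List of variance-dataset parameters; see
#'   [generate_variance_dataset()].
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200, replicates_per_age = 2)
#' str(cfg$strata)
sim_config <- function(seed = 1L,
                       strains = c("B6", "NZO"),
                       tissues = c("PBL", "spleen", "naiveCD8", "memoryCD8"),
                       strata = NULL,
                       ages_months = c(3, 18),
                       replicates_per_age = 6L,
                       n_genes = 5000L,
                       planted_conserved = list(genes = NULL, log2fc = 2),
                       planted_strain_specific = NULL,
                       dispersion = NULL,
                       library_size_range = c(1e6, 3e6),
                       baseline_log2_mean_range = c(-18, -9),
                       regulatory = list(),
                       composition = list(),
                       variance = list()) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid sim_config field '%s': %s", field, msg))
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single finite number")
  chk(length(strains) >= 1 && !anyDuplicated(strains),
      "strains", "must be unique labels")
  chk(length(tissues) >= 1 && !anyDuplicated(tissues),
      "tissues", "must be unique labels")
  if (is.null(strata)) {
    strata <- tidyr::expand_grid(strain = strains, tissue = tissues)
  }
  chk(all(c("strain", "tissue") %in% names(strata)),
      "strata", "needs strain and tissue columns")
  chk(length(ages_months) >= 2 && all(ages_months > 0) &&
        !anyDuplicated(ages_months),
      "ages_months", "needs >= 2 distinct positive ages")
  chk(replicates_per_age >= 2, "replicates_per_age", "must be >= 2")
  chk(n_genes >= 1, "n_genes", "must be positive")
  chk(all(library_size_range > 0) && length(library_size_range) == 2,
      "library_size_range", "must be two positive numbers")
  chk(length(baseline_log2_mean_range) == 2 &&
        all(is.finite(baseline_log2_mean_range)),
      "baseline_log2_mean_range", "must be two finite numbers")

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(planted_conserved$genes)) {
    planted_conserved$genes <- head(gene_ids, min(5L, n_genes))
  }
  if (is.null(planted_strain_specific)) {
    pool <- setdiff(gene_ids, planted_conserved$genes)
    planted_strain_specific <- list()
    for (i in seq_along(strains)) {
      take <- head(pool, min(5L, length(pool)))
      pool <- setdiff(pool, take)
      planted_strain_specific[[strains[i]]] <-
        list(genes = take, log2fc = 2)
    }
  }
  planted_sets <- c(list(planted_conserved$genes),
                    lapply(planted_strain_specific, `[[`, "genes"))
  all_planted <- unlist(planted_sets)
  chk(!anyDuplicated(all_planted), "planted_conserved/planted_strain_specific",
      "planted gene sets must be disjoint")
  chk(all(all_planted %in% gene_ids), "planted genes",
      "planted ids must be among the simulated gene ids")
  effects <- c(planted_conserved$log2fc,
               unlist(lapply(planted_strain_specific, `[[`, "log2fc")))
  chk(all(is.finite(effects)), "log2fc", "all effects must be finite")
  if (!is.null(dispersion)) {
    chk(all(dispersion >= 0) &&
          (length(dispersion) %in% c(1L, n_genes)),
        "dispersion", "must be >= 0, scalar or per-gene")
  }

  reg_default <- list(
    chrom = "chrS", chrom_length = 1e7, n_peaks = 600L,
    peak_width = c(300L, 800L), frac_opening = 0.15, frac_closing = 0.15,
    n_samples_per_group = 3L, peak_detect_prob = 0.85,
    tf_roster = c("Jun", "Fos", sprintf("TF%02d", 1:18)),
    aging_tfs = c("Jun", "Fos"), aging_multiplier = 3,
    footprints_per_group = 10000L, footprint_width = c(10L, 25L),
    purity_shape = c(8, 2), cut_tfs = c("Jun", "Fos"),
    cut_background_rate = 0.2, cut_peak_height = 6, cut_peak_sd = 20,
    cut_flank = 200L)
  comp_default <- list(
    cell_types = tibble(
      cell_type = c("naiveCD8", "memoryCD8", "B", "monocytes"),
      intercept = c(43, 17, 32, 8),
      slope = c(-1.0, 1.0, -0.3, 0.4)),
    noise_sd = 3, animals_per_age = replicates_per_age)
  var_default <- list(
    factors = list(tissue = paste0("T", 1:4), strain = c("A", "B"),
                   age = c("young", "old")),
    sigma2 = c(tissue = 0.55, strain = 0.2, age = 0.05),
    sigma2_residual = 0.2,
    n_features = 500L, replicates = 2L)

  cfg <- list(
    seed = as.integer(seed), strains = strains, tissues = tissues,
    strata = as_tibble(strata), ages_months = sort(ages_months),
    replicates_per_age = as.integer(replicates_per_age),
    n_genes = as.integer(n_genes), gene_ids = gene_ids,
    planted_conserved = planted_conserved,
    planted_strain_specific = planted_strain_specific,
    dispersion = dispersion,
    library_size_range = library_size_range,
    baseline_log2_mean_range = baseline_log2_mean_range,
    regulatory = shallow_modify(reg_default, regulatory),
    composition = shallow_modify(comp_default, composition),
    variance = shallow_modify(var_default, variance))
  if (any(cfg$variance$sigma2 < 0) || cfg$variance$sigma2_residual < 0) {
    abort("Invalid sim_config field 'variance': sigma2 values must be >= 0")
  }
  if (cfg$composition$noise_sd < 0) {
    abort("Invalid sim_config field 'composition': noise_sd must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a cross-strain, cross-tissue aging expression study
#'
#' Draws negative-binomial counts for every stratum (strain x tissue) in
#' the configuration. The per-gene mean in sample \eqn{s} of a stratum is
#' \deqn{\mu_{gs} = L_s \, 2^{\,b_g + \beta_{g}\,(a_s - a_{min})/(a_{max} - a_{min})}}
#' where \eqn{L_s} is the library size, \eqn{b_g} the baseline log2
#' relative abundance and \eqn{\beta_g} the planted log2 fold-change over
#' the full age span (0 for null genes). Counts are NB with per-gene
#' dispersion \eqn{\phi_g}.
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (wide tibble, `feature` + one column per
#'   sample), `samples` (sample metadata tibble) and `truth` (per-gene,
#'   per-stratum true log2 fold-changes plus gene-level attributes).
#' @export
#' @examples
#' sim <- generate_study(sim_config(seed = 1, n_genes = 50,
#'                                  replicates_per_age = 2))
#' dim(sim$counts)
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- config$gene_ids
    baseline <- runif(G, config$baseline_log2_mean_range[1],
                      config$baseline_log2_mean_range[2])
    phi <- config$dispersion
    if (is.null(phi)) {
      phi <- rgamma(G, shape = 2, scale = 0.1 / 2)
    } else if (length(phi) == 1) {
      phi <- rep(phi, G)
    }
    ages <- config$ages_months
    amin <- min(ages); amax <- max(ages)

    # per-stratum true effects
    effect <- matrix(0, G, nrow(config$strata),
                     dimnames = list(genes, NULL))
    pc <- config$planted_conserved
    effect[match(pc$genes, genes), ] <- pc$log2fc
    for (str_name in names(config$planted_strain_specific)) {
      ps <- config$planted_strain_specific[[str_name]]
      cols <- which(config$strata$strain == str_name)
      effect[match(ps$genes, genes), cols] <- ps$log2fc
    }

    counts_list <- list()
    sample_rows <- list()
    for (k in seq_len(nrow(config$strata))) {
      strn <- config$strata$strain[k]
      tiss <- config$strata$tissue[k]
      design <- tidyr::expand_grid(age_months = ages,
                                   rep = seq_len(config$replicates_per_age))
      ns <- nrow(design)
      ids <- sprintf("%s_%s_m%02d_r%d", strn, tiss,
                     design$age_months, design$rep)
      lib <- round(runif(ns, config$library_size_range[1],
                         config$library_size_range[2]))
      sexes <- rep_len(c("F", "M"), ns)
      frac_age <- (design$age_months - amin) / (amax - amin)
      log2mu <- outer(baseline, rep(1, ns)) +
        effect[, k] %o% frac_age
      mu <- sweep(2^log2mu, 2, lib, `*`)
      cnt <- matrix(rnbinom(G * ns, mu = mu, size = 1 / pmax(phi, 1e-12)),
                    G, ns)
      dimnames(cnt) <- list(genes, ids)
      counts_list[[k]] <- cnt
      sample_rows[[k]] <- tibble(
        sample_id = ids, strain = strn, tissue = tiss,
        age_months = design$age_months, sex = sexes,
        library_size_nominal = lib)
    }
    counts <- do.call(cbind, counts_list)
    samples <- bind_rows(sample_rows)

    colnames(effect) <- stratum_label(config$strata$strain,
                                      config$strata$tissue)
    truth_effects <- as_tibble(effect) |>
      mutate(feature = genes, .before = 1) |>
      tidyr::pivot_longer(-"feature", names_to = "stratum",
                          values_to = "true_log2fc_span")
    truth <- list(
      effects = truth_effects,
      genes = tibble(feature = genes, baseline_log2 = baseline,
                     dispersion = phi),
      planted_conserved = pc$genes,
      planted_strain_specific =
        lapply(config$planted_strain_specific, `[[`, "genes"))
    list(counts = matrix_to_counts(counts), samples = samples,
         truth = truth)
  })
}

#' Simulate a synthetic regulatory landscape
#'
#' Generates a master peak set on one synthetic chromosome, per-sample
#' peak calls with controllable cross-sample overlap, TF footprint calls
#' with purity scores, and per-base cut-site signal (Poisson background
#' plus a Gaussian-shaped enrichment centred on each footprint) over the
#' neighbourhoods of the footprints of the TFs named in `cut_tfs`
#' (the profile-plot use case; positions outside these windows carry
#' zero signal). Designated "aging" TFs place their
#' footprints preferentially inside opening peaks in old-animal groups,
#' with odds multiplied by `aging_multiplier`.
#'
#' @param config A [sim_config()] object; see the `regulatory` block.
#' @return A list with `peaks` (master truth: chrom/start/end/peak_id/
#'   class), `sample_peaks` (per-sample calls), `footprints` (TF calls
#'   with purity and group metadata), and `cut_signal` (group, pos,
#'   count; positions not listed carry zero signal).
#' @export
generate_regulatory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rg <- config$regulatory
  with_seed(config$seed + 1L, {
    L <- rg$chrom_length
    npk <- rg$n_peaks
    w <- round(runif(npk, rg$peak_width[1], rg$peak_width[2]))
    gap <- L / (npk + 1)
    if (gap <= max(rg$peak_width) + 2 * rg$cut_flank) {
      abort("Regulatory generation error: chromosome too short for the requested peaks.")
    }
    start <- round(seq_len(npk) * gap - w / 2)
    end <- start + w
    if (any(start < 0) || any(end > L)) {
      abort("Regulatory generation error: peak coordinates overflow the chromosome.")
    }
    cls <- sample(c("opening", "closing", "stable"), npk, replace = TRUE,
                  prob = c(rg$frac_opening, rg$frac_closing,
                           1 - rg$frac_opening - rg$frac_closing))
    peaks <- tibble(chrom = rg$chrom, start = start, end = end,
                    peak_id = sprintf("peak_%04d", seq_len(npk)),
                    class = cls)

    # per-sample peak calls: each sample detects each master peak with
    # probability peak_detect_prob, with small boundary jitter
    groups <- tidyr::expand_grid(
      strain = config$strains,
      tissue = unique(config$strata$tissue),
      age_group = c("young", "old"))
    sample_peaks <- purrr::pmap_dfr(groups, function(strain, tissue, age_group) {
      purrr::map_dfr(seq_len(rg$n_samples_per_group), function(r) {
        keep <- runif(npk) < rg$peak_detect_prob
        jit <- round(rnorm(sum(keep), 0, 10))
        tibble(chrom = rg$chrom,
               start = pmax(0, peaks$start[keep] + jit),
               end = peaks$end[keep] + jit,
               sample_id = sprintf("%s_%s_%s_s%d", strain, tissue,
                                   age_group, r),
               strain = strain, tissue = tissue, age_group = age_group)
      })
    })

    # footprints: sample a TF then a peak, with aging TFs in old groups
    # favouring opening peaks by the configured multiplier
    ntf <- length(rg$tf_roster)
    fps <- purrr::pmap_dfr(groups, function(strain, tissue, age_group) {
      nfp <- rg$footprints_per_group
      tf <- sample(rg$tf_roster, nfp, replace = TRUE)
      mult <- ifelse(tf %in% rg$aging_tfs & age_group == "old",
                     rg$aging_multiplier, 1)
      # two-stage draw: peak class by multiplied odds, then a uniform
      # peak within the class (equivalent to weighted peak sampling)
      open_idx <- which(peaks$class == "opening")
      rest_idx <- which(peaks$class != "opening")
      p_open <- mult * length(open_idx) /
        (mult * length(open_idx) + length(rest_idx))
      in_open <- runif(nfp) < p_open
      pick <- integer(nfp)
      pick[in_open] <- sample(open_idx, sum(in_open), replace = TRUE)
      pick[!in_open] <- sample(rest_idx, sum(!in_open), replace = TRUE)
      fw <- round(runif(nfp, rg$footprint_width[1], rg$footprint_width[2]))
      span <- pmax((peaks$end[pick] - peaks$start[pick]) - fw, 1)
      s0 <- peaks$start[pick] + round(runif(nfp, 0, span))
      tibble(tf = tf, chrom = rg$chrom, start = s0, end = s0 + fw,
             purity = rbeta(nfp, rg$purity_shape[1], rg$purity_shape[2]),
             strain = strain, tissue = tissue, age_group = age_group,
             group = paste(strain, tissue, age_group, sep = ":"),
             peak_id = peaks$peak_id[pick],
             peak_class = peaks$class[pick])
    })
    if (any(fps$end <= fps$start) || any(fps$start < 0) ||
        any(fps$end > L)) {
      abort("Regulatory generation error: footprint coordinates overflow.")
    }
    fps <- arrange(fps, .data$group, .data$start)

    # cut-site signal over footprint neighbourhoods only; elsewhere the
    # background is zero by construction of the sparse representation
    flank <- rg$cut_flank
    offs <- -flank:flank
    bump <- rg$cut_peak_height * exp(-offs^2 / (2 * rg$cut_peak_sd^2))
    cut_signal <- fps |>
      filter(.data$tf %in% rg$cut_tfs) |>
      group_by(.data$group) |>
      dplyr::group_modify(function(d, key) {
        centers <- unique(floor((d$start + d$end) / 2))
        # stack each centre's Gaussian contribution, then sum by base
        pos_all <- rep(centers, each = length(offs)) + offs
        lam_all <- rep(bump, length(centers))
        ok <- pos_all >= 0 & pos_all < L
        agg <- rowsum(lam_all[ok], pos_all[ok])
        pos <- as.numeric(rownames(agg))
        o <- order(pos)
        lam <- agg[o, 1] + rg$cut_background_rate
        tibble(chrom = rg$chrom, pos = pos[o],
               count = rpois(length(lam), lam))
      }) |>
      ungroup()

    list(peaks = peaks, sample_peaks = sample_peaks,
         footprints = fps, cut_signal = cut_signal,
         truth = list(aging_tfs = rg$aging_tfs,
                      aging_multiplier = rg$aging_multiplier))
  })
}

#' Simulate cell-type composition percentages
#'
#' Per-animal percentages follow `intercept + slope * age` plus Gaussian
#' noise, clipped to \[0, 100\]. Cell types are generated independently
#' (their percentages need not sum to 100, mirroring independent gating).
#'
#' @param config A [sim_config()] object; see the `composition` block.
#' @return Long tibble: animal_id, strain, tissue, age_months, sex,
#'   cell_type, percent.
#' @export
generate_composition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$composition
  if (cp$noise_sd < 0) abort("noise_sd must be >= 0.")
  with_seed(config$seed + 2L, {
    design <- tidyr::expand_grid(
      strain = config$strains,
      tissue = unique(config$strata$tissue),
      age_months = config$ages_months,
      rep = seq_len(cp$animals_per_age))
    design$animal_id <- sprintf("%s_%s_m%02d_a%d", design$strain,
                                design$tissue, design$age_months,
                                design$rep)
    design$sex <- rep_len(c("F", "M"), nrow(design))
    out <- tidyr::expand_grid(design, cp$cell_types) |>
      mutate(percent = pmin(100, pmax(0,
        .data$intercept + .data$slope * .data$age_months +
          rnorm(n(), 0, cp$noise_sd)))) |>
      select("animal_id", "strain", "tissue", "age_months", "sex",
             "cell_type", "percent")
    out
  })
}

#' Simulate a dataset with known variance components
#'
#' Each feature is a sum of independent random level effects, one per
#' design factor, plus Gaussian residual noise:
#' \eqn{x_{fs} = \sum_k u_{f,k,\mathrm{level}_k(s)} + \varepsilon_{fs}},
#' with \eqn{u \sim N(0, \sigma^2_k)} drawn fresh per feature. The truth
#' records the variance fractions \eqn{\sigma^2_k / \sum \sigma^2}.
#'
#' @param config A [sim_config()] object; see the `variance` block.
#' @return List with `features` (wide tibble, feature x samples),
#'   `factors` (sample_id + one column per factor) and `truth`
#'   (tibble factor, true_fraction; includes "residual").
#' @export
generate_variance_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vr <- config$variance
  if (any(vr$sigma2 < 0) || vr$sigma2_residual < 0) {
    abort("Variance components must be >= 0.")
  }
  with_seed(config$seed + 3L, {
    grid <- tidyr::expand_grid(!!!vr$factors,
                               .rep = seq_len(vr$replicates))
    ns <- nrow(grid)
    grid$sample_id <- sprintf("s%03d", seq_len(ns))
    fac_names <- names(vr$factors)
    G <- vr$n_features
    X <- matrix(rnorm(G * ns, 0, sqrt(vr$sigma2_residual)), G, ns)
    for (fn in fac_names) {
      lv <- vr$factors[[fn]]
      idx <- match(grid[[fn]], lv)
      u <- matrix(rnorm(G * length(lv), 0, sqrt(vr$sigma2[[fn]])),
                  G, length(lv))
      X <- X + u[, idx, drop = FALSE]
    }
    rownames(X) <- sprintf("feat_%04d", seq_len(G))
    colnames(X) <- grid$sample_id
    total <- sum(vr$sigma2) + vr$sigma2_residual
    truth <- tibble(
      factor = c(fac_names, "residual"),
      true_fraction = c(unname(vr$sigma2[fac_names]),
                        vr$sigma2_residual) / total)
    list(features = matrix_to_counts(X),
         factors = select(grid, "sample_id", dplyr::all_of(fac_names)),
         truth = truth)
  })
}
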