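#' Filter features by counts-per-million expression
#'
#' Keeps features whose CPM (count / library size x 1e6) is at least
#' `2^min_log2cpm` in at least `min_samples` samples; the defaults drop
#' features with log2 CPM < 1 (CPM < 2) in all but one sample. Library
#' sizes are the raw column totals unless supplied.
#'
#' @param counts Wide counts tibble (`feature` + one column per sample).
#' @param min_log2cpm Minimum log2 CPM (default 1, i.e. CPM >= 2).
#' @param min_samples Minimum number of samples meeting the CPM cut.
#' @param lib_sizes Optional named per-sample library sizes.
#' @return Filtered counts tibble.
#' @export
#' @examples
#' counts <- tibble::tibble(feature = c("a", "b"),
#'                          s1 = c(3L, 1L), s2 = c(3L, 0L))
#' cpm_filter(counts, lib_sizes = c(s1 = 1e6, s2 = 1e6))
cpm_filter <- function(counts, min_log2cpm = 1, min_samples = 2,
                       lib_sizes = NULL) {
  m <- validate_counts(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  lib_sizes <- lib_sizes[colnames(m)]
  if (any(!is.finite(lib_sizes) | lib_sizes <= 0)) {
    abort("All library sizes must be positive.")
  }
  cpm <- sweep(m, 2, lib_sizes, `/`) * 1e6
  keep <- rowSums(cpm >= 2^min_log2cpm) >= min_samples
  if (!any(keep)) {
    abort("CPM filter removed every feature; nothing left to analyse.")
  }
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors (trimmed mean of M-values
#' against the sample whose 75th-percentile CPM is closest to the mean
#' 75th percentile), rescaled to geometric mean 1. The computation is
#' delegated to the standard edgeR implementation; `logratio_trim` and
#' `abs_trim` follow its published defaults.
#'
#' @param counts Wide counts tibble.
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param abs_trim Two-sided trim fraction on absolute expression.
#' @return Tibble sample_id / lib_size / tmm_factor.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- validate_counts(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(m)
  if (any(lib <= 0)) abort("Every sample must have a positive total count.")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  if (any(!is.finite(f) | f <= 0)) {
    abort("TMM failed: no commonly expressed genes with the reference sample.")
  }
  tibble(sample_id = colnames(m), lib_size = unname(lib),
         tmm_factor = unname(f))
}

# Method-of-moments NB dispersion from a fitted mean matrix, with a
# residual-df inflation factor n / (n - p).
mom_dispersion <- function(Y, Mu, p) {
  n <- ncol(Y)
  num <- rowSums((Y - Mu)^2 - Mu)
  den <- rowSums(Mu^2)
  pmax((num / den) * n / max(n - p, 1), 0)
}

#' Per-feature negative-binomial age association within a stratum
#'
#' For each feature in one strain x tissue stratum, fits an NB GLM with
#' log link, continuous age (months) and optional covariates, with
#' offset `log(lib_size x TMM factor)`. Dispersion is estimated per
#' feature by method of moments on the Poisson-fit residuals, floored at
#' 1e-8 and shrunk 50/50 toward the median dispersion, then held fixed
#' for the final fit. The age coefficient is tested with a Wald
#' statistic referred to a t distribution with residual degrees of
#' freedom; p-values are BH-adjusted within the stratum. A covariate
#' that makes the design singular (e.g. sex confounded with age) is
#' dropped with a warning. Non-converged fits are reported with p = 1.
#'
#' @param counts Wide counts tibble (already CPM-filtered as desired).
#' @param samples Sample metadata tibble.
#' @param stratum Stratum selector: a list/one-row data frame with
#'   `strain` and `tissue`, or `NULL` to use all samples as one stratum.
#' @param covariates Character vector of metadata columns to adjust for.
#' @param lib_sizes,norm_factors Optional named per-sample overrides;
#'   computed from the stratum counts (TMM) by default.
#' @param shrink_weight Weight on the per-feature dispersion (the
#'   remainder goes to the median); default 0.5.
#' @return Tibble: feature, beta (natural-log slope per month),
#'   log2fc_span (slope rescaled to the min-to-max age span, in log2),
#'   se, p, fdr, mean_log2cpm, converged, stratum.
#' @export
fit_age_association <- function(counts, samples, stratum = NULL,
                                covariates = "sex",
                                lib_sizes = NULL, norm_factors = NULL,
                                shrink_weight = 0.5) {
  m_all <- validate_counts(counts, samples)
  if (!is.null(stratum)) {
    sel <- samples$strain == stratum$strain &
      samples$tissue == stratum$tissue
    samples <- samples[sel, , drop = FALSE]
    label <- stratum_label(stratum$strain, stratum$tissue)
  } else {
    label <- "all"
  }
  if (nrow(samples) < 4) {
    abort(sprintf("Stratum %s has fewer than 4 samples.", label))
  }
  ages <- samples$age_months
  if (length(unique(ages)) < 2) {
    abort(sprintf("Stratum %s has a constant age; the age effect is not estimable.",
                  label))
  }
  Y <- m_all[, samples$sample_id, drop = FALSE]

  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(Y)
  } else {
    lib_sizes <- rep_len(lib_sizes, ncol(Y))
  }
  if (is.null(norm_factors)) {
    nf <- tmm_factors(matrix_to_counts(Y))
    norm_factors <- nf$tmm_factor[match(colnames(Y), nf$sample_id)]
  } else {
    norm_factors <- rep_len(norm_factors, ncol(Y))
  }
  offset <- log(lib_sizes * norm_factors)

  # design: intercept + age + covariates, dropping singular columns
  X <- cbind(`(Intercept)` = 1, age_months = ages)
  for (cv in covariates) {
    vals <- samples[[cv]]
    if (is.null(vals)) next
    if (length(unique(vals)) < 2) next
    mm <- stats::model.matrix(~vals)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
    cand <- cbind(X, mm)
    if (qr(cand)$rank == ncol(cand)) {
      X <- cand
    } else {
      warn(sprintf("Covariate '%s' is confounded with the design in stratum %s; dropped.",
                   cv, label))
    }
  }
  p <- ncol(X)

  # pass 1: Poisson fit to estimate dispersion by moments
  fit0 <- fit_nb_glm_cpp(Y, X, offset, rep(0, nrow(Y)))
  phi_raw <- mom_dispersion(Y, fit0$mu, p)
  phi_raw <- pmax(phi_raw, 1e-8)
  phi <- shrink_weight * phi_raw +
    (1 - shrink_weight) * median(phi_raw)

  # pass 2: NB fit at the fixed shrunken dispersion
  fit <- fit_nb_glm_cpp(Y, X, offset, phi)
  age_col <- which(colnames(X) == "age_months")
  beta <- fit$beta[, age_col]
  se <- fit$se[, age_col]
  conv <- as.logical(fit$converged) & is.finite(se) & se > 0
  tstat <- ifelse(conv, beta / se, 0)
  df <- max(ncol(Y) - p, 1)
  pval <- ifelse(conv, 2 * pt(-abs(tstat), df = df), 1)

  span <- max(ages) - min(ages)
  cpm <- sweep(Y, 2, lib_sizes, `/`) * 1e6
  tibble(
    feature = rownames(Y),
    beta = unname(beta),
    log2fc_span = unname(beta) * span / log(2),
    se = unname(se),
    p = unname(pval),
    fdr = bh_adjust(unname(pval)),
    mean_log2cpm = unname(rowMeans(log2(cpm + 0.5))),
    converged = unname(conv),
    stratum = label)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differential features
#'
#' A feature is differential iff `fdr < fdr_max` and
#' `|log2fc_span| > min_abs_log2fc` (both strict), with direction given
#' by the sign of the fold change ("up"/opening vs "down"/closing).
#'
#' @param results Age-association tibble from [fit_age_association()].
#' @param fdr_max FDR threshold (strict `<`).
#' @param min_abs_log2fc Absolute log2 fold-change threshold (strict `>`).
#' @return `results` with logical `called` and `direction` columns.
#' @export
call_differential <- function(results, fdr_max = 0.05,
                              min_abs_log2fc = 1) {
  stopifnot(all(c("fdr", "log2fc_span") %in% names(results)))
  mutate(as_tibble(results),
         called = .data$fdr < fdr_max &
           abs(.data$log2fc_span) > min_abs_log2fc,
         direction = dplyr::case_when(
           !.data$called ~ "none",
           .data$log2fc_span > 0 ~ "up",
           TRUE ~ "down"))
}

#' Age association across all strata of a study
#'
#' Convenience wrapper running [cpm_filter()] and
#' [fit_age_association()] within every strain x tissue stratum.
#'
#' @inheritParams fit_age_association
#' @param min_log2cpm,min_samples CPM filter settings (per stratum).
#' @param fdr_max,min_abs_log2fc Differential-call thresholds.
#' @return Tibble of per-feature results across strata with strain and
#'   tissue columns and differential calls.
#' @export
fit_all_strata <- function(counts, samples, covariates = "sex",
                           min_log2cpm = 1, min_samples = 2,
                           fdr_max = 0.05, min_abs_log2fc = 1,
                           shrink_weight = 0.5) {
  strata <- distinct(samples, .data$strain, .data$tissue)
  purrr::pmap_dfr(strata, function(strain, tissue) {
    sel <- samples$strain == strain & samples$tissue == tissue
    sub_samples <- samples[sel, , drop = FALSE]
    sub_counts <- counts[, c("feature", sub_samples$sample_id)]
    sub_counts <- cpm_filter(sub_counts, min_log2cpm, min_samples)
    res <- fit_age_association(sub_counts, sub_samples,
                               stratum = list(strain = strain,
                                              tissue = tissue),
                               covariates = covariates,
                               shrink_weight = shrink_weight)
    res <- call_differential(res, fdr_max, min_abs_log2fc)
    mutate(res, strain = strain, tissue = tissue)
  })
}
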