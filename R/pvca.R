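#' Principal variance component analysis
#'
#' Attributes data variance to metadata factors by combining PCA with
#' per-PC random-effect variance components. Features are standardised
#' (centred and scaled) so the attribution is invariant to feature
#' units; the sample-sample covariance of the standardised matrix is
#' eigendecomposed, and the smallest number of leading PCs whose
#' cumulative eigenvalue share reaches `var_threshold` is retained (at
#' least `min_pcs`). For each retained PC a random-intercept model with
#' one random effect per factor is fitted by REML (lme4); if REML
#' fails, a non-negative method-of-moments estimator on the per-level
#' group means is used instead. Per-PC variance proportions
#' \eqn{\hat\sigma^2_k / \sum \hat\sigma^2} are averaged across PCs
#' with eigenvalue weights.
#'
#' @param features Wide numeric tibble (`feature` + one column per
#'   sample) or a features x samples matrix.
#' @param factors Tibble with `sample_id` and one column per design
#'   factor (all treated as categorical).
#' @param var_threshold Cumulative eigenvalue share to capture.
#' @param min_pcs Minimum number of PCs retained.
#' @return A `magsig_pvca` object: `proportions` tibble
#'   (factor, proportion), per-PC detail, eigenvalue weights, PCs used
#'   and cumulative variance captured.
#' @export
#' @examples
#' sim <- generate_variance_dataset(sim_config(seed = 1))
#' pv <- pvca_decompose(sim$features, sim$factors)
#' tidy(pv)
pvca_decompose <- function(features, factors, var_threshold = 0.6,
                           min_pcs = 3) {
  X <- if (is.matrix(features)) features else counts_to_matrix(features)
  fac <- as_tibble(factors)
  stopifnot("sample_id" %in% names(fac))
  fac <- fac[match(colnames(X), fac$sample_id), , drop = FALSE]
  if (anyNA(fac$sample_id)) {
    abort("Every sample in `features` needs a row in `factors`.")
  }
  fac_names <- setdiff(names(fac), "sample_id")
  usable <- fac_names[vapply(fac_names, function(f)
    length(unique(fac[[f]])) > 1, logical(1))]
  dropped <- setdiff(fac_names, usable)
  if (length(dropped) > 0) {
    warn(sprintf("Factors with a single level dropped: %s",
                 paste(dropped, collapse = ", ")))
  }
  if (length(usable) == 0) abort("All factors were dropped; nothing to attribute.")

  # standardise features; constant features carry no information
  sds <- apply(X, 1, sd)
  keep <- is.finite(sds) & sds > 0
  Xs <- scale(t(X[keep, , drop = FALSE]))  # samples x features
  S <- cov(t(Xs))                          # sample-sample covariance
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  share <- ev / sum(ev)
  n_pc <- max(min_pcs, which(cumsum(share) >= var_threshold)[1])
  n_pc <- min(n_pc, sum(ev > 1e-12))

  per_pc <- purrr::map_dfr(seq_len(n_pc), function(i) {
    y <- eg$vectors[, i]
    comps <- pvca_components_one_pc(y, fac, usable)
    tibble(pc = i, eigenvalue = ev[i], factor = names(comps),
           sigma2 = unname(comps))
  })
  per_pc <- per_pc |>
    group_by(.data$pc) |>
    mutate(proportion = .data$sigma2 / sum(.data$sigma2)) |>
    ungroup()
  wts <- ev[seq_len(n_pc)] / sum(ev[seq_len(n_pc)])
  props <- per_pc |>
    group_by(.data$factor) |>
    summarise(proportion = sum(.data$proportion * wts[.data$pc]),
              .groups = "drop") |>
    arrange(match(.data$factor, c(usable, "residual")))

  structure(list(
    proportions = props, per_pc = per_pc, pcs_used = n_pc,
    eigenvalue_weights = wts,
    cumulative_variance = sum(share[seq_len(n_pc)]),
    factors = usable), class = "magsig_pvca")
}

# Variance components for one PC score vector: REML random intercepts,
# with a non-negative method-of-moments fallback.
pvca_components_one_pc <- function(y, fac, fac_names) {
  dat <- data.frame(.y = y, fac[, fac_names, drop = FALSE])
  form <- stats::as.formula(paste(
    ".y ~ 1 +", paste(sprintf("(1 | %s)", fac_names), collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    comps <- setNames(vc$vcov, vc$grp)
    names(comps)[names(comps) == "Residual"] <- "residual"
    return(comps[c(fac_names, "residual")] |>
             setNames(c(fac_names, "residual")))
  }
  # fallback: one-way MoM per factor, residual from the pooled
  # within-group variance of the finest cross-classification
  comps <- vapply(fac_names, function(f) {
    g <- fac[[f]]
    mu <- tapply(y, g, mean)
    nbar <- mean(table(g))
    msb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2)) /
      (length(mu) - 1)
    msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) /
      (length(y) - length(mu))
    max((msb - msw) / nbar, 0)
  }, numeric(1))
  resid <- max(var(y) - sum(comps), 0)
  c(comps, residual = resid)
}

#' @export
print.magsig_pvca <- function(x, ...) {
  cat(sprintf("PVCA over %d PCs (%.1f%% of variance)\n", x$pcs_used,
              100 * x$cumulative_variance))
  print(x$proportions)
  invisible(x)
}

#' Tidy a PVCA result
#' @param x A `magsig_pvca` object.
#' @param ... Unused.
#' @return Tibble factor / proportion.
#' @export
tidy.magsig_pvca <- function(x, ...) x$proportions

#' Glance at a PVCA result
#' @inheritParams tidy.magsig_pvca
#' @return One-row tibble: pcs_used, cumulative_variance, n_factors.
#' @export
glance.magsig_pvca <- function(x, ...) {
  tibble(pcs_used = x$pcs_used,
         cumulative_variance = x$cumulative_variance,
         n_factors = length(x$factors))
}

#' Plot PVCA variance attributions
#' @param object A `magsig_pvca` object.
#' @param ... Unused.
#' @return A ggplot bar chart of proportions per factor.
#' @export
autoplot.magsig_pvca <- function(object, ...) {
  d <- mutate(object$proportions,
              factor = stats::reorder(.data$factor, -.data$proportion))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor,
                                  y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "Weighted variance proportion",
                  title = sprintf("PVCA (%d PCs, %.0f%% variance)",
                                  object$pcs_used,
                                  100 * object$cumulative_variance)) +
    ggplot2::theme_minimal()
}
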