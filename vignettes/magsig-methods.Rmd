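---
title: "Conserved immune-aging signatures with magsig: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved immune-aging signatures with magsig: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsig)
library(dplyr)
```

## The problem

Transcriptional and chromatin changes with age are noisy, tissue-specific
and strain-specific. A change observed in one inbred mouse strain in one
tissue may be idiosyncratic; a change that reappears in a second,
genetically distant strain and across several immune compartments is a
candidate *conserved* aging signature. `magsig` implements a complete
desk-scale pipeline for finding such signatures: per-stratum
negative-binomial age-association modelling of count data (RNA-seq genes
or ATAC-seq peaks), rank aggregation of per-stratum significance into a
single conservation score (the MAG score), preranked gene-set enrichment
on that score, variance attribution (PVCA), module over-representation,
transcription-factor footprint statistics, and linear age trends in
cell-type composition. A seeded synthetic-data generator emulates the
study design — two strains (a standard B6-like and an obese NZO-like
strain) crossed with four immune compartments (PBL, spleen, naive and
memory CD8 T cells) at 3 and 18 months — so that every stage can be
exercised and validated against planted ground truth.

## Age-association model

Within one stratum (strain × tissue), counts \(y_{gs}\) for feature
\(g\) in sample \(s\) follow a negative-binomial GLM with log link:

\[
\log \mu_{gs} = \beta_{0g} + \beta_{1g}\,\mathrm{age}_s +
  \boldsymbol\gamma_g^\top \mathbf{z}_s + \log(L_s f_s),
\qquad \operatorname{Var}(y_{gs}) = \mu_{gs} + \phi_g \mu_{gs}^2 ,
\]

with age in months treated as continuous, optional covariates
\(\mathbf z_s\) (sex by default; dropped automatically with a warning if
confounded with the design), library size \(L_s\) and TMM normalization
factor \(f_s\) as offset. Fold changes are reported on the span scale,
`log2fc_span` \(= \hat\beta_1 (a_{\max} - a_{\min}) / \ln 2\), so a
continuous-age fit is directly comparable to an old-versus-young
contrast (here, over the 15-month span).

Dispersion is estimated per feature by method of moments on the
residuals of a Poisson first pass,
\(\hat\phi_g = \max\!\big(0, \tfrac{n}{n-p}\,
\sum_s[(y_{gs}-\hat\mu_{gs})^2-\hat\mu_{gs}] / \sum_s \hat\mu_{gs}^2\big)\),
floored at \(10^{-8}\) and shrunk half-way toward the median dispersion
across features — a deliberately simple stabiliser for small-\(n\)
designs (the shrinkage weight is exposed). The age coefficient is tested
with a Wald statistic. We refer it to a *t* distribution with
\(n - p\) residual degrees of freedom rather than a standard normal:
with six animals per age group the normal reference is anticalibrated,
while the *t* reference keeps the empirical type-I error at
\(\alpha = 0.05\) inside \([0.035, 0.065]\) in the null simulations the
test suite runs. This is an approximation, not a reimplementation of
any particular published tool; exact empirical-Bayes dispersion
machinery and quasi-likelihood F-tests are out of scope.

Features are pre-filtered by expression: a feature is kept when its CPM
exceeds \(2^{\texttt{min\_log2cpm}}\) (default log2 CPM ≥ 1, i.e.
CPM ≥ 2) in at least `min_samples` (default 2) samples. The filter's
log base is a frequent source of ambiguity in methods descriptions; we
adopt log2 and expose the threshold directly. Differential calls use
strict thresholds `fdr < 0.05` and `|log2fc_span| > 1`.

## MAG conservation score

Each stratum's results are ranked by ascending p-value (rank 1 = most
significant), with ties broken by larger |log2fc| and then gene id so
ranking is deterministic. The ranking key deliberately ignores the
direction of change; direction is tracked separately and reported as a
consensus ("up", "down", "mixed") so that direction-discordant genes
are visible rather than silently excluded.

For gene \(g\) in tissue \(t\), the MAG (magnitude of association)
score is the geometric mean of inverse ranks across the \(S\) strains,

\[
m_t(g) = \Big( \prod_{s=1}^{S} \frac{1}{r_{g,s,t}} \Big)^{1/S},
\qquad
M_g = \sum_{t} m_t(g),
\]

and genes are finally ranked by descending \(M_g\). A gene must be
close to the top in *both* strains to score well in a tissue (geometric
mean), and consistently so across tissues to lead the final ranking
(sum). Genes filtered out of a stratum receive the worst-plus-one rank
\(n_{\text{tested}} + 1\) there, so non-conservation is penalised
instead of the gene being dropped; an intersection-only mode
(`absent_rank = "drop"`) is available. MAG is computed over all tested
genes, not only differential ones.

## Preranked GSEA

The MAG-descending list is scanned with the classic running-sum
statistic: set members increment the sum by \(|M_g|^w / \sum_{set}
|M|^w\) (weight exponent \(w = 1\) by default; \(w = 0\) gives the
unweighted statistic), non-members decrement it by \(1/(N - n_{set})\).
The enrichment score ES is the maximum of the running sum — enrichment
at the top of the ranking, the only direction of interest for a
conservation score — and 0 when the sum never rises above zero. The
null distribution places the \(n_{set}\) labels uniformly at random on
the list; \(p = (1 + \#\{ES_{null} \ge ES\}) / (1 + n_{perm})\), and
\(NES = ES / \overline{ES_{null}^{+}}\) (mean of strictly positive null
scores). When `exhaustive = TRUE` and \(\binom{N}{n_{set}} \le 10^5\)
the null is enumerated completely, which the test suite uses as its own
oracle. Ties at the observed ES are counted as at-least-as-extreme,
with a \(10^{-12}\) numerical tolerance so that mathematically tied
placements are not split by floating-point summation order. The leading
edge is the set members at or before the running-sum maximum.

These are the dominant preranked conventions; published GSEA tools vary
in weighting and normalization details, so numerical identity with any
one of them is not a goal, and all choices are exposed as arguments.

## PVCA

Variance attribution standardises features, eigendecomposes the
sample-sample covariance and retains the smallest number of leading PCs
reaching 60% cumulative eigenvalue share (at least 3; both exposed).
Each retained PC score vector is modelled with one random intercept per
design factor (REML via `lme4`; a non-negative method-of-moments
fallback covers REML failures), age entering as a categorical factor.
Per-PC variance proportions \(\hat\sigma^2_k / \sum\hat\sigma^2\) are
averaged with eigenvalue weights. Proportions always form a probability
vector.

Two caveats that the recovery simulations make explicit. First, a
factor with \(L\) levels spans \(L-1\) PCs, so when one factor has many
levels the retention threshold can exhaust itself on that factor's
subspace and under-represent the others; the packaged recovery checks
therefore use two-level factors (the study's own strain and age-group
structure), where 0.6/0.3/0.1 variance fractions are recovered within
±0.10 in ≥90% of seeds. Second, because retained leading PCs are
signal-dominated, the residual share is systematically conservative
(biased low) — pure-noise data is still attributed ≥90% to the
residual. Interactions are not modelled (main effects only).

## Regulatory statistics

All interval logic is 0-based half-open; book-ended intervals do not
overlap and never merge. Consensus peaks merge strictly-overlapping
per-sample intervals into maximal regions and keep regions supported by
at least 2 distinct samples (the support threshold is exposed). Peaks
are annotated to the nearest TSS by centre distance with a signed,
strand-aware offset (positive = downstream) and a ±2 kb promoter flag —
the window is our default, exposed as an argument. Footprints are
filtered at purity (positive-predictive value) strictly > 0.9.

TF enrichment in opening/closing peaks is a bias-naive upper-tail
hypergeometric test: for each TF, the foreground (opening or closing)
peaks containing at least one footprint of the TF are tested against
the age-stable background peaks; containment is binary, not
count-weighted. Published footprint-enrichment methods additionally
correct for read-depth and GC bias using read-level data that this
package deliberately does not model — this replacement is the largest
simplification in the package and is stated here prominently. The
"supported in at least two" reporting rule is applied at the stratum
level (a TF is pan-stratum when q < 0.05 in ≥ 2 strata), since pooled
strata are our unit of analysis. Aggregate cut-site profiles average
per-base cut counts over ±100 bp around footprint centres and divide by
the group's total cut count; locus reports count footprints within
±100 kb of a gene's TSS.

## Cell-composition trends

Per cell type and stratum, ordinary least squares of raw percentage on
age in months, a two-sided *t*-test on the slope, and BH correction
across the cell types of the stratum (the FDR family is exposed).
Percentages are fitted untransformed; sibling cell types are modelled
independently and need not sum to 100. Zero-residual fits return the
exact slope with the p-value flagged unavailable rather than a
spuriously perfect significance.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 2 strains × 4 tissues, ages
3 and 18 months, 6 animals per age, 5000 genes, 5 planted conserved
genes with a log2 fold-change of 2 over the age span (applied in every
stratum) plus 5 strain-specific genes per strain, NB dispersion drawn
per gene from gamma(shape 2, mean 0.1) — a typical bulk RNA-seq range —
or fixed (0.1 in the recovery checks), library sizes uniform on
[1e6, 3e6], and baseline log2 relative abundances uniform on [−18, −9]
so that the CPM filter is active. Counts are drawn as
\(y \sim NB(L_s 2^{b_g + \beta_g \tilde a_s}, \phi_g)\) with
\(\tilde a_s\) the age scaled to [0, 1] over the span, so the planted
log2fc is exactly the old-versus-young effect.

The regulatory generator places 600 peaks on one 10 Mb synthetic
chromosome (one chromosome keeps interval bookkeeping simple while
exercising all interval logic), classes them opening/closing/stable
(15/15/70%), emits per-sample peak calls with 85% detection and small
boundary jitter, and drops 10,000 footprints per (strain, tissue,
age-group) pool over a 20-TF roster — the scale at which the
purity-filtered per-TF counts resemble genome-wide footprint scans.
Two designated aging TFs (named Jun and Fos after the canonical AP-1
subunits) multiply their odds of landing in opening peaks by 3 in old
groups. Purity scores are Beta(8, 2), so the 0.9 filter removes about
three quarters of calls and is genuinely non-trivial. Cut-site signal
(Poisson background 0.2/bp plus Gaussian bumps, height 6, sd 20 bp,
centred on footprints) is generated over ±200 bp neighbourhoods of the
aging TFs' footprints — the aggregate-profile use case; positions
outside these windows carry zero signal by construction. The generator
does not model sequence content, mappability, GC structure or
read-level data, so passing tests demonstrate statistical correctness
of the pipeline, not robustness to those real-data biases.

Composition percentages follow `intercept + slope × age` plus Gaussian
noise (sd 3), clipped to [0, 100]; the default panel plants a declining
naive CD8 fraction (−1 %/month) and a rising memory CD8 fraction
(+1 %/month), echoing the best-established compositional hallmark of
immune aging. The variance-dataset generator draws each feature as a
sum of per-level Gaussian effects plus residual noise and records the
true variance fractions.

All generators are fully determined by the seed; identical
configurations are byte-identical across runs.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen once as the smallest
sizes at which the statistical properties are unambiguous: 5000 genes ×
12 samples per stratum for recovery (20 seeds), 2000 genes for null
calibration, 500 features × 24 samples for PVCA (20 seeds), complete
GSEA enumeration up to \(N = 8\), exact hypergeometric margins up to
\(N = 25\), and 10,000 permutations for GSEA p-values. Non-converged
GLM fits (IRLS, relative deviance tolerance \(10^{-10}\), 50
iterations) are reported with p = 1 rather than dropped. The end-to-end
pipeline writes TSV outputs plus a JSON manifest with MD5 hashes of
every output, and is hash-reproducible under a fixed seed.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 2000, replicates_per_age = 6,
                  dispersion = 0.1)
sim <- generate_study(cfg)
assoc <- fit_all_strata(sim$counts, sim$samples)
ranks <- assoc |>
  group_by(stratum) |>
  group_modify(~rank_stratum(.x)) |>
  ungroup()
mag <- mag_scores(ranks)
head(mag[order(mag$final_rank), c("feature", "mag", "final_rank")])
gsea <- preranked_gsea(mag, cfg$planted_conserved$genes,
                       n_perm = 10000, seed = 1)
autoplot(gsea)
```

The planted conserved genes occupy the top MAG ranks and their set is
strongly enriched; `scripts/acceptance.R` recomputes these recovery
rates (alongside oracle-agreement and calibration quantities) from
scratch.

## Known limitations

- The Wald/t inference is approximate; it is validated by calibration,
  not by agreement with any reference differential-expression tool.
- Footprint enrichment ignores read-count and GC bias entirely.
- PVCA's residual attribution is conservative by construction, and
  attribution degrades when factors with many levels dominate the
  retained PC subspace.
- The generator's independence assumptions (independent genes,
  independent cell-type percentages) understate the correlation
  structure of real data.
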