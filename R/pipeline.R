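#' Default pipeline configuration
#'
#' Assembles a full pipeline configuration around a synthetic study.
#' All analysis thresholds default to the study's printed values
#' (FDR 0.05, |log2FC| > 1, footprint purity 0.9, peak support 2,
#' locus window 100 kb) and every stage can be toggled.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param outdir Output directory.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param stages Character vector of stages to run.
#' @param params Named list of threshold overrides (fdr_max,
#'   min_abs_log2fc, min_log2cpm, min_samples, min_purity, min_support,
#'   promoter_window, locus_window, n_perm, var_threshold, min_pcs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("magsig_run_"),
                            sim = NULL,
                            stages = c("simulate", "diffassoc", "mag",
                                       "gsea", "enrich", "pvca",
                                       "peaks", "footprints",
                                       "composition"),
                            params = list()) {
  defaults <- list(fdr_max = 0.05, min_abs_log2fc = 1, min_log2cpm = 1,
                   min_samples = 2, min_purity = 0.9, min_support = 2,
                   promoter_window = 2000, locus_window = 1e5,
                   n_perm = 10000, var_threshold = 0.6, min_pcs = 3,
                   gsea_weight = 1)
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    sim = sim %||% sim_config(seed = seed),
    stages = stages,
    params = modifyList(defaults, params)), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain `seed`, `outdir`, `stages`, a `params` block
#' and a `sim` block of [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  sim_args$seed <- sim_args$seed %||% (y$seed %||% 1L)
  pipeline_config(
    seed = y$seed %||% 1L,
    outdir = y$outdir %||% tempfile("magsig_run_"),
    sim = do.call(sim_config, sim_args),
    stages = y$stages %||% formals(pipeline_config)$stages |> eval(),
    params = y$params %||% list())
}

write_stage_tsv <- function(x, outdir, name) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic study
#' (simulate, per-stratum age association, MAG aggregation, preranked
#' GSEA on the planted conserved set, module enrichment of differential
#' genes, PVCA, consensus peaks, footprint statistics, composition
#' trends), writing one TSV per output and a JSON manifest recording
#' each stage's status, parameters, seed and output file MD5 hashes.
#' A stage failure aborts the run with the failing stage named; the
#' manifest retains completed stages and a FAILED marker.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pars <- config$params
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, outputs) {
    hashes <- as.list(tools::md5sum(unlist(outputs)))
    names(hashes) <- basename(names(hashes))
    manifest$stages[[stage]] <<- list(
      status = "COMPLETE", outputs = lapply(outputs, basename),
      md5 = hashes)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    inform(sprintf("[magsig] stage %s ...", stage))
    tryCatch(fn(), error = function(e) {
      manifest$stages[[stage]] <<- list(status = "FAILED",
                                        error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  run_stage("simulate", function() {
    sim <- generate_study(config$sim)
    state$sim <- sim
    p1 <- write_stage_tsv(sim$counts, config$outdir, "counts")
    p2 <- write_stage_tsv(sim$samples, config$outdir, "samples")
    p3 <- write_stage_tsv(sim$truth$effects, config$outdir,
                          "truth_effects")
    inform(sprintf("[magsig]   %d genes x %d samples",
                   nrow(sim$counts), nrow(sim$samples)))
    record("simulate", list(p1, p2, p3))
  })

  run_stage("diffassoc", function() {
    sim <- state$sim
    res <- fit_all_strata(sim$counts, sim$samples,
                          min_log2cpm = pars$min_log2cpm,
                          min_samples = pars$min_samples,
                          fdr_max = pars$fdr_max,
                          min_abs_log2fc = pars$min_abs_log2fc)
    state$assoc <- res
    inform(sprintf("[magsig]   %d differential calls across %d strata",
                   sum(res$called), length(unique(res$stratum))))
    record("diffassoc",
           list(write_stage_tsv(res, config$outdir, "age_association")))
  })

  run_stage("mag", function() {
    ranks <- state$assoc |>
      group_by(.data$stratum) |>
      dplyr::group_modify(~rank_stratum(.x)) |>
      ungroup()
    mag <- mag_scores(ranks)
    state$mag <- mag
    record("mag", list(write_stage_tsv(mag, config$outdir, "mag_scores")))
  })

  run_stage("gsea", function() {
    set <- config$sim$planted_conserved$genes
    gs <- preranked_gsea(state$mag, set,
                         weight_exponent = pars$gsea_weight,
                         n_perm = pars$n_perm,
                         seed = derive_seeds(config$seed, 1))
    state$gsea <- gs
    inform(sprintf("[magsig]   GSEA ES %.3f NES %.3f p %.4g",
                   gs$es, gs$nes, gs$p))
    p1 <- write_stage_tsv(tidy(gs), config$outdir, "gsea_result")
    p2 <- write_stage_tsv(gs$running, config$outdir, "gsea_running")
    record("gsea", list(p1, p2))
  })

  run_stage("enrich", function() {
    sim <- state$sim
    assoc <- state$assoc
    universe <- unique(assoc$feature)
    de_up <- unique(assoc$feature[assoc$called & assoc$log2fc_span > 0])
    modules <- c(list(conserved_aging = sim$truth$planted_conserved),
                 setNames(sim$truth$planted_strain_specific,
                          paste0("strain_specific_",
                                 names(sim$truth$planted_strain_specific))))
    if (length(de_up) == 0) {
      warn("No upregulated differential genes; skipping enrichment table.")
      manifest$stages[["enrich"]] <<- list(status = "COMPLETE",
                                           outputs = list(), md5 = list())
      return(invisible(NULL))
    }
    enr <- hypergeom_enrich(de_up, modules, universe,
                            fdr_max = pars$fdr_max)
    record("enrich",
           list(write_stage_tsv(enr, config$outdir, "module_enrichment")))
  })

  run_stage("pvca", function() {
    sim <- state$sim
    m <- counts_to_matrix(sim$counts)
    lib <- colSums(m)
    logcpm <- log2(sweep(m, 2, lib, `/`) * 1e6 + 0.5)
    keep <- order(apply(logcpm, 1, var), decreasing = TRUE)
    keep <- head(keep, min(1000, nrow(logcpm)))
    fac <- sim$samples |>
      mutate(age = as.character(.data$age_months)) |>
      select("sample_id", "tissue", "strain", "age", "sex")
    pv <- pvca_decompose(logcpm[keep, , drop = FALSE], fac,
                         var_threshold = pars$var_threshold,
                         min_pcs = pars$min_pcs)
    state$pvca <- pv
    record("pvca",
           list(write_stage_tsv(tidy(pv), config$outdir,
                                "pvca_proportions")))
  })

  run_stage("peaks", function() {
    reg <- generate_regulatory(config$sim)
    state$reg <- reg
    consensus <- build_consensus_peaks(reg$sample_peaks,
                                       min_support = pars$min_support)
    state$consensus <- consensus
    record("peaks",
           list(write_stage_tsv(consensus, config$outdir,
                                "consensus_peaks")))
  })

  run_stage("footprints", function() {
    reg <- state$reg %||% generate_regulatory(config$sim)
    fps <- footprint_filter(reg$footprints,
                            min_purity = pars$min_purity) |>
      mutate(stratum = stratum_label(.data$strain, .data$tissue))
    old_fps <- filter(fps, .data$age_group == "old")
    pk <- reg$peaks
    enr <- footprint_peak_enrichment(
      old_fps,
      opening_peaks = filter(pk, .data$class == "opening"),
      closing_peaks = filter(pk, .data$class == "closing"),
      background_peaks = filter(pk, .data$class == "stable"))
    prop <- footprint_proportions(fps)
    opened <- enr |>
      filter(.data$direction == "opening", .data$enriched)
    shared <- shared_tf_sets(split(opened$tf, opened$stratum))
    p1 <- write_stage_tsv(enr, config$outdir, "footprint_enrichment")
    p2 <- write_stage_tsv(prop, config$outdir, "footprint_proportions")
    p3 <- write_stage_tsv(shared$combinations, config$outdir,
                          "shared_tf_sets")
    record("footprints", list(p1, p2, p3))
  })

  run_stage("composition", function() {
    comp <- generate_composition(config$sim)
    trends <- fit_composition_trends(comp, fdr_max = pars$fdr_max)
    record("composition",
           list(write_stage_tsv(comp, config$outdir, "composition"),
                write_stage_tsv(trends, config$outdir,
                                "composition_trends")))
  })

  manifest$params <- pars
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
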