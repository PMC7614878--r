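#' Assemble and validate a pipeline configuration
#'
#' Collects everything [run_pipeline()] needs. The cohort comes either
#' from a [sim_config()] (simulated on the fly) or from `input_dir`, a
#' directory written by [write_cohort()]. Landscapes are either read
#' from `key_landscape_dir` / `refinement_landscape_dir` or, by
#' default, built from an independently simulated reference cohort
#' under the same design (sub-seed derived from `seed`).
#'
#' @param outdir output directory for stage artifacts.
#' @param sim a `sim_config`, or `NULL` when `input_dir` is given.
#' @param input_dir cohort directory to load instead of simulating.
#' @param qc a [qc_thresholds()].
#' @param score_layer layer signatures are scored on ("scaled" or
#'   "logcounts").
#' @param seed master integer seed; every stochastic stage derives its
#'   own sub-seed from it.
#' @param key_landscape_dir,refinement_landscape_dir optional
#'   serialized landscapes ([write_landscape()]).
#' @param k neighbors for label transfer.
#' @param candidates candidate genes for p53-dependence calling.
#' @param min_types,alpha dependence-calling parameters.
#' @param genotype_roles named vector mapping wt / mutant /
#'   mutant_p53null to genotype labels.
#' @param survival_n,survival_hr,survival_frac_high,survival_censor
#'   parameters of the simulated survival cohort.
#' @param quantile_q top-score fraction for survival stratification.
#' @param covariates Cox covariates (beyond the score group).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            sim = NULL,
                            input_dir = NULL,
                            qc = qc_thresholds(min_genes = 100,
                                               max_pct_mito = 0.1),
                            score_layer = "scaled",
                            seed = 1L,
                            key_landscape_dir = NULL,
                            refinement_landscape_dir = NULL,
                            k = 15L,
                            candidates = haem_p53_genes,
                            min_types = 3L,
                            alpha = 0.05,
                            genotype_roles = c(wt = "WT", mutant = "DKO",
                                               mutant_p53null = "TKO"),
                            survival_n = 1000L,
                            survival_hr = 2.34,
                            survival_frac_high = 0.25,
                            survival_censor = 0.3,
                            quantile_q = 0.25,
                            covariates = c("age_gt60", "prior_treatment")) {
  if (is.null(sim) && is.null(input_dir))
    stop("provide either 'sim' (a sim_config) or 'input_dir'")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config")
  for (d in c(input_dir, key_landscape_dir, refinement_landscape_dir))
    if (!is.null(d) && !dir.exists(d)) stop("path does not exist: ", d)
  structure(list(outdir = outdir, sim = sim, input_dir = input_dir,
                 qc = qc, score_layer = score_layer, seed = as.integer(seed),
                 key_landscape_dir = key_landscape_dir,
                 refinement_landscape_dir = refinement_landscape_dir,
                 k = as.integer(k), candidates = candidates,
                 min_types = as.integer(min_types), alpha = alpha,
                 genotype_roles = genotype_roles,
                 survival_n = as.integer(survival_n),
                 survival_hr = survival_hr,
                 survival_frac_high = survival_frac_high,
                 survival_censor = survival_censor,
                 quantile_q = quantile_q, covariates = covariates),
            class = "pipeline_config")
}

# coarse labels used when building the two-tier landscapes from a
# simulated reference: the stem compartment collapses to "HSC"
.coarse_label <- function(types, lineage) {
  ifelse(lineage[types] == "stem", "HSC", types)
}

.stage <- function(report, name, expr, params = "") {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("stage=%s elapsed=%.2fs %s", name,
                  as.numeric(Sys.time() - t0, units = "secs"), params))
  report$manifest <- rbind(report$manifest,
                           data.frame(stage = name, parameters = params,
                                      stringsAsFactors = FALSE))
  report[[name]] <- value
  report
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: cohort simulation/loading, cell QC,
#' normalization to 10K, log transform, scaling, two-tier reference
#' cell typing, aging and p53 signature scoring, p53-dependence
#' calling, lineage proportions, and score-stratified survival
#' analysis. Each stage appends a manifest line and writes its artifact
#' under `config$outdir`; a rerun with the same config and seed
#' reproduces identical score columns.
#'
#' @param config a [pipeline_config()].
#' @return a run-report list holding every stage result plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  report <- list(manifest = data.frame(stage = character(),
                                       parameters = character()))

  report <- .stage(report, "input", {
    if (!is.null(config$input_dir))
      list(sce = read_matrix(config$input_dir), cell_truth = NULL)
    else simulate_hspc_cohort(config$sim)
  }, if (!is.null(config$input_dir)) paste0("dir=", config$input_dir)
     else paste0("seed=", config$sim$seed))
  sce <- report$input$sce

  report <- .stage(report, "qc", {
    sce <- qc_filter_cells(compute_cell_qc(sce), config$qc, verbose = FALSE)
    S4Vectors::metadata(sce)$qc_log
  }, sprintf("cells_in=%d", ncol(report$input$sce)))

  report <- .stage(report, "layers", {
    sce <- scale_genes(log_transform(normalize_counts(sce)))
    SummarizedExperiment::assayNames(sce)
  }, "target_sum=10000")

  report <- .stage(report, "annotate", {
    if (!is.null(config$key_landscape_dir)) {
      key <- read_landscape(config$key_landscape_dir)
      refn <- if (!is.null(config$refinement_landscape_dir))
        read_landscape(config$refinement_landscape_dir) else NULL
    } else {
      if (is.null(config$sim))
        stop("no landscapes supplied and no sim design to build them from")
      lds <- build_reference_landscapes(config$sim,
                                        seed = config$seed + 1000L)
      key <- lds$key; refn <- lds$refinement
    }
    typing <- hierarchical_cell_typing(sce, key, refn, k = config$k)
    SummarizedExperiment::colData(sce)$assigned_type <- typing$label
    typing
  }, sprintf("k=%d", config$k))

  report <- .stage(report, "score", {
    aging <- aging_signature_score(sce, layer = config$score_layer,
                                   seed = config$seed)
    p53 <- haem_p53_score(sce, layer = config$score_layer,
                          seed = config$seed)
    cd <- SummarizedExperiment::colData(sce)
    cd$aging_signature <- aging$score
    cd$haem_p53 <- p53$score
    SummarizedExperiment::colData(sce) <- cd
    scores <- data.frame(cell_id = colnames(sce),
                         aging_signature = aging$score,
                         haem_p53 = p53$score)
    write.table(scores, file.path(outdir, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(aging = aging, p53 = p53)
  }, sprintf("layer=%s seed=%d", config$score_layer, config$seed))

  report <- .stage(report, "dependence", {
    calls <- identify_p53_dependent_genes(
      sce, candidates = config$candidates,
      genotypes = config$genotype_roles,
      min_types = config$min_types, alpha = config$alpha)
    write.table(calls, file.path(outdir, "dependence_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  }, sprintf("min_types=%d alpha=%g", config$min_types, config$alpha))

  report <- .stage(report, "proportions", {
    lineage_map <- if (!is.null(config$sim)) config$sim$cell_types
      else stop("lineage map requires a sim design")
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    # roll up on true simulated types; assigned types may be coarser
    tab <- lineage_proportions(meta, lineage_map)
    write.csv(tab$by_type, file.path(outdir, "lineage_proportions.csv"),
              row.names = FALSE)
    tab
  })

  report <- .stage(report, "survival", {
    cohort <- simulate_survival_cohort(config$survival_n,
                                       hr_high = config$survival_hr,
                                       frac_high = config$survival_frac_high,
                                       censor_rate = config$survival_censor,
                                       seed = config$seed + 2000L)
    strat <- stratify_top_quantile(
      stats::setNames(cohort$score, cohort$subject_id), q = config$quantile_q)
    km <- kaplan_meier(cohort, strat$group)
    lr <- logrank_test_hr(cohort, strat$group)
    cohort$score_high <- as.integer(strat$group == "high")
    cox <- cox_fit(cohort, c("score_high", config$covariates))
    write.csv(km, file.path(outdir, "km_table.csv"), row.names = FALSE)
    write.csv(data.frame(hr = lr$hr, ci_low = lr$ci_low,
                         ci_high = lr$ci_high, p = lr$p),
              file.path(outdir, "logrank_stats.csv"), row.names = FALSE)
    write.csv(cox, file.path(outdir, "cox_fit.csv"), row.names = FALSE)
    list(cohort = cohort, stratification = strat, km = km, logrank = lr,
         cox = cox)
  }, sprintf("n=%d hr=%g q=%g", config$survival_n, config$survival_hr,
             config$quantile_q))

  report$sce <- sce
  write.table(report$manifest, file.path(outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

#' Build two-tier reference landscapes from a simulation design
#'
#' Simulates an annotated reference cohort under `sim` and keeps the
#' cells of `ref_genotype` (conventionally the wild type, so planted
#' disease effects do not shape the reference geometry), then fits: a
#' key landscape over all reference cells with the stem
#' compartment collapsed to "HSC", and a refinement landscape over the
#' stem cells with their fine labels. HVGs are taken by spike-in
#' calibrated selection with a dispersion-based fallback.
#'
#' @param sim a [sim_config()].
#' @param seed seed for the reference simulation.
#' @param n_components PCA components (capped by the reference size).
#' @param ref_genotype genotype whose cells form the reference; the
#'   default (first genotype, conventionally the wild type) keeps
#'   planted disease effects out of the reference geometry.
#' @return list with `key` and `refinement` landscapes and the
#'   reference `sce`.
#' @export
build_reference_landscapes <- function(sim, seed = 1001L,
                                       n_components = 50L,
                                       ref_genotype = sim$genotypes[1]) {
  ref_cfg <- sim
  ref_cfg$seed <- as.integer(seed)
  ref <- simulate_hspc_cohort(ref_cfg)
  keep <- ref$cell_truth$genotype == ref_genotype
  if (!any(keep)) stop("reference genotype has no cells: ", ref_genotype)
  sce <- scale_genes(log_transform(normalize_counts(ref$sce[, keep])))
  hvg <- tryCatch(select_hvg_spikein(sce),
                  error = function(e) fallback_hvg_dispersion(sce))
  hvgs <- hvg$gene[hvg$selected]
  if (length(hvgs) < 20) {  # sparse selections give an unstable basis
    fb <- fallback_hvg_dispersion(sce)
    hvgs <- union(hvgs, fb$gene[fb$selected])
  }
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  coarse <- .coarse_label(meta$cell_type, sim$cell_types)
  nc <- min(n_components, length(hvgs), ncol(sce) - 1L)
  key <- fit_reference_pca(sce, coarse, hvgs, n_components = nc)
  stem <- coarse == "HSC"
  refinement <- NULL
  if (sum(stem) > 2) {
    nc2 <- min(n_components, length(hvgs), sum(stem) - 1L)
    refinement <- fit_reference_pca(sce[, stem], meta$cell_type[stem],
                                    hvgs, n_components = nc2)
  }
  list(key = key, refinement = refinement, sce = sce)
}

#' Write a packaged miniature fixture set
#'
#' Generates a deterministic small cohort (92 spike-ins, well under
#' 2,000 cells and 1,500 genes), the two reference landscapes, and a
#' simulated survival cohort, exercising every pipeline stage.
#'
#' @param outdir writable output directory.
#' @param seed integer seed; identical seeds give identical trees.
#' @param n_per_type cells per (genotype, cell type).
#' @param n_genes biological genes in the miniature transcriptome.
#' @return `outdir`, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L, n_per_type = 30L,
                          n_genes = 600L) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outdir)
  cfg <- default_hspc_config(n_per_type = n_per_type, n_genes = n_genes,
                             seed = seed)
  cohort <- simulate_hspc_cohort(cfg)
  write_cohort(cohort, file.path(outdir, "cohort"))
  lds <- build_reference_landscapes(cfg, seed = seed + 1000L,
                                    n_components = 20L)
  write_landscape(lds$key, file.path(outdir, "landscape_key"))
  if (!is.null(lds$refinement))
    write_landscape(lds$refinement, file.path(outdir, "landscape_refine"))
  surv <- simulate_survival_cohort(300L, seed = seed + 2000L)
  write.csv(surv, file.path(outdir, "survival_cohort.csv"),
            row.names = FALSE)
  invisible(outdir)
}
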