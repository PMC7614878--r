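#' Simulation configuration for a synthetic HSPC cohort
#'
#' Bundles and validates everything [simulate_hspc_cohort()] needs:
#' the genotype-by-cell-type design, per-gene negative-binomial baselines,
#' planted multiplicative effects, and spike-in settings.
#'
#' Counts are drawn NB with variance \eqn{\mu + \mu^2/\theta}
#' (mean/dispersion parameterization, the standard for scRNA-seq counts);
#' per-cell size factors are lognormal(0, `library_size_spread`) and
#' multiply biological means only, so spike-in counts stay pure technical
#' noise independent of cell type and genotype.
#'
#' @param genotypes character vector of genotype labels (unique).
#' @param cell_types named character vector: names are cell-type labels,
#'   values their lineage class (`"stem"`, `"myeloid"` or `"lymphoid"`).
#' @param n_cells_per_type integer; either a single count used for every
#'   (genotype, cell type) pair, or a genotype x cell-type matrix with
#'   dimnames matching `genotypes` and `names(cell_types)`.
#' @param baseline_means named positive numeric, one NB mean per gene;
#'   names are the gene symbols of the simulated transcriptome.
#' @param dispersion positive numeric, NB size parameter theta
#'   (scalar or one per gene).
#' @param effect_table data.frame of planted effects with columns
#'   `set`, `gene`, `genotype`, `cell_type`, `fold_change`; `"*"` in
#'   `genotype`/`cell_type` matches every level. See [effect_entry()].
#' @param p53_set name of the effect set whose presence defines the
#'   per-cell "p53-active" ground-truth flag.
#' @param n_spikeins number of ERCC-like spike-in species.
#' @param spikein_means positive numeric, recycled over spike-ins.
#' @param library_size_spread lognormal sigma (>= 0) of cell size factors.
#' @param seed integer seed; (config, seed) fully determines the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genotypes,
                       cell_types,
                       n_cells_per_type,
                       baseline_means,
                       dispersion = 2,
                       effect_table = NULL,
                       p53_set = "p53",
                       n_spikeins = 92,
                       spikein_means = NULL,
                       library_size_spread = 0.3,
                       seed = 1L) {
  if (length(genotypes) < 1L || anyDuplicated(genotypes))
    stop("'genotypes' must be a non-empty vector of unique labels")
  if (length(cell_types) < 1L || is.null(names(cell_types)) ||
      anyDuplicated(names(cell_types)))
    stop("'cell_types' must be a non-empty named vector with unique labels")
  if (!all(cell_types %in% c("stem", "myeloid", "lymphoid")))
    stop("lineage classes must be 'stem', 'myeloid' or 'lymphoid'")
  if (is.null(names(baseline_means)) || anyDuplicated(names(baseline_means)))
    stop("'baseline_means' must be named with unique gene symbols")
  if (any(!is.finite(baseline_means)) || any(baseline_means <= 0))
    stop("all baseline means must be positive")
  if (any(!is.finite(dispersion)) || any(dispersion <= 0))
    stop("all dispersions must be positive")
  if (!length(dispersion) %in% c(1L, length(baseline_means)))
    stop("'dispersion' must be scalar or one value per gene")
  if (library_size_spread < 0) stop("'library_size_spread' must be >= 0")
  if (n_spikeins < 0) stop("'n_spikeins' must be >= 0")
  if (is.null(spikein_means))
    spikein_means <- if (n_spikeins > 0)
      2^seq(-2, 9, length.out = n_spikeins) else numeric(0)
  if (n_spikeins > 0 && any(spikein_means <= 0))
    stop("all spike-in means must be positive")

  types <- names(cell_types)
  if (is.matrix(n_cells_per_type)) {
    if (!identical(sort(rownames(n_cells_per_type)), sort(genotypes)) ||
        !identical(sort(colnames(n_cells_per_type)), sort(types)))
      stop("dimnames of 'n_cells_per_type' must match genotypes and cell types")
    ncells <- n_cells_per_type[genotypes, types, drop = FALSE]
  } else {
    if (length(n_cells_per_type) != 1L || n_cells_per_type < 0)
      stop("'n_cells_per_type' must be a single count or a matrix")
    ncells <- matrix(as.integer(n_cells_per_type),
                     nrow = length(genotypes), ncol = length(types),
                     dimnames = list(genotypes, types))
  }
  if (sum(ncells) < 1L) stop("design contains no cells")

  effect_table <- .validate_effects(effect_table, genotypes, types,
                                    names(baseline_means))
  structure(list(
    genotypes = genotypes, cell_types = cell_types,
    n_cells_per_type = ncells, baseline_means = baseline_means,
    dispersion = rep_len(dispersion, length(baseline_means)),
    effect_table = effect_table, p53_set = p53_set,
    n_spikeins = as.integer(n_spikeins), spikein_means = spikein_means,
    library_size_spread = library_size_spread, seed = as.integer(seed)),
    class = "sim_config")
}

.validate_effects <- function(effect_table, genotypes, types, genes) {
  if (is.null(effect_table) || nrow(effect_table) == 0L)
    return(data.frame(set = character(), gene = character(),
                      genotype = character(), cell_type = character(),
                      fold_change = numeric()))
  need <- c("set", "gene", "genotype", "cell_type", "fold_change")
  if (!all(need %in% colnames(effect_table)))
    stop("effect_table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(effect_table$fold_change)) ||
      any(effect_table$fold_change <= 0))
    stop("all fold-changes must be positive")
  bad_g <- setdiff(effect_table$genotype, c(genotypes, "*"))
  if (length(bad_g)) stop("unknown genotype in effect_table: ",
                          paste(bad_g, collapse = ", "))
  bad_t <- setdiff(effect_table$cell_type, c(types, "*"))
  if (length(bad_t)) stop("unknown cell type in effect_table: ",
                          paste(bad_t, collapse = ", "))
  bad_gene <- setdiff(effect_table$gene, genes)
  if (length(bad_gene)) stop("effect_table genes absent from baseline_means: ",
                             paste(head(bad_gene, 5), collapse = ", "))
  effect_table[need]
}

#' Build effect-table rows for one planted effect
#'
#' @param set effect-set name (used for ground-truth flags).
#' @param genes character vector of target genes.
#' @param genotype genotype label or `"*"`.
#' @param cell_type cell-type label(s) or `"*"`.
#' @param fold_change multiplicative effect (> 0).
#' @return data.frame with one row per (gene, cell_type).
#' @export
effect_entry <- function(set, genes, genotype, cell_type, fold_change) {
  expand.grid(set = set, gene = genes, genotype = genotype,
              cell_type = cell_type, fold_change = fold_change,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Default study configuration for the simulated HSPC cohort
#'
#' Encodes the cohort structure the package's analyses assume: three
#' genotypes (wild type `"WT"`; a DNA-damage double knockout `"DKO"` with
#' an activated p53 response; the same background with p53 additionally
#' deleted, `"TKO"`), six HSPC types spanning stem, lymphoid and myeloid
#' lineage classes, a 4-fold activation of the 16 hematopoietic p53
#' target genes in DKO cells (absent in TKO, i.e. rescued by p53 loss),
#' and a 3-fold rise of the 20 aging-signature genes in DKO stem cells.
#' Five mitochondrial (`mt-`) genes are included so mitochondrial QC
#' fractions are well defined, and per-cell-type marker blocks (default
#' 6-fold over 25 genes each) give the transcriptome the cluster
#' structure that reference projection relies on.
#'
#' @param n_per_type cells per (genotype, cell type), or a design matrix
#'   as in [sim_config()].
#' @param n_genes total number of biological genes (>= 300).
#' @param p53_fc,aging_fc,marker_fc planted fold-changes.
#' @param extra_effects optional extra effect rows rbound to the default
#'   effect table (see [effect_entry()]).
#' @param seed integer seed.
#' @inheritParams sim_config
#' @return a `sim_config`.
#' @export
default_hspc_config <- function(n_per_type = 100L,
                                n_genes = 1000L,
                                p53_fc = 4,
                                aging_fc = 3,
                                marker_fc = 6,
                                extra_effects = NULL,
                                library_size_spread = 0.3,
                                seed = 1L) {
  if (n_genes < 300L) stop("'n_genes' must be at least 300")
  genotypes <- c("WT", "DKO", "TKO")
  cell_types <- c("LT-HSC" = "stem", "ST-HSC" = "stem", "MPP" = "stem",
                  "LMPP" = "lymphoid", "GMP" = "myeloid", "MEP" = "myeloid")
  special <- c(haem_p53_genes, aging_signature_genes,
               paste0("mt-", c("Co1", "Co2", "Co3", "Nd1", "Cytb")))
  n_marker <- 25L
  markers <- lapply(names(cell_types), function(ct)
    paste0("Mk", gsub("[^A-Za-z0-9]", "", ct), sprintf("%02d", seq_len(n_marker))))
  names(markers) <- names(cell_types)
  n_bg <- n_genes - length(special) - n_marker * length(cell_types)
  genes <- c(special, unlist(markers, use.names = FALSE),
             sprintf("Gene%04d", seq_len(n_bg)))
  means <- with_local_seed(seed + 104729L,
                           rlnorm(length(genes), meanlog = log(0.8), sdlog = 1.2))
  means <- pmin(means, 50)
  names(means) <- genes
  # signature genes get a moderate, comfortably detectable baseline
  means[haem_p53_genes] <- 2
  means[aging_signature_genes] <- 2
  means[startsWith(genes, "mt-")] <- 20
  for (ct in names(cell_types)) means[markers[[ct]]] <- 1.5

  eff <- rbind(
    effect_entry("p53", haem_p53_genes, "DKO", "*", p53_fc),
    effect_entry("aging", aging_signature_genes, "DKO",
                 c("LT-HSC", "ST-HSC", "MPP"), aging_fc),
    do.call(rbind, lapply(names(cell_types), function(ct)
      effect_entry(paste0("marker_", ct), markers[[ct]], "*", ct, marker_fc)))
  )
  if (!is.null(extra_effects)) eff <- rbind(eff, extra_effects)

  sim_config(genotypes = genotypes, cell_types = cell_types,
             n_cells_per_type = n_per_type, baseline_means = means,
             dispersion = 2, effect_table = eff, p53_set = "p53",
             n_spikeins = 92L, library_size_spread = library_size_spread,
             seed = seed)
}

#' Cell-count design matrix with a planted myeloid expansion
#'
#' Distributes `n_per_genotype` cells so that the myeloid lineage class
#' holds a given fraction per genotype (split evenly within lineage
#' classes), emulating the myeloid-biased composition of the
#' DNA-damage genotypes.
#'
#' @param cell_types named lineage-class vector as in [sim_config()].
#' @param n_per_genotype named integer, total cells per genotype.
#' @param myeloid_frac named fraction of myeloid cells per genotype.
#' @return genotype x cell-type integer matrix.
#' @export
myeloid_biased_design <- function(cell_types,
                                  n_per_genotype = c(WT = 500L, DKO = 500L,
                                                     TKO = 500L),
                                  myeloid_frac = c(WT = 0.3, DKO = 0.6,
                                                   TKO = 0.6)) {
  stopifnot(identical(names(n_per_genotype), names(myeloid_frac)))
  mye <- names(cell_types)[cell_types == "myeloid"]
  oth <- setdiff(names(cell_types), mye)
  if (!length(mye) || !length(oth))
    stop("design needs both myeloid and non-myeloid cell types")
  out <- matrix(0L, nrow = length(n_per_genotype), ncol = length(cell_types),
                dimnames = list(names(n_per_genotype), names(cell_types)))
  for (g in names(n_per_genotype)) {
    n_m <- round(n_per_genotype[[g]] * myeloid_frac[[g]])
    out[g, mye] <- .split_count(n_m, length(mye))
    out[g, oth] <- .split_count(n_per_genotype[[g]] - n_m, length(oth))
  }
  out
}

.split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}

#' Simulate an HSPC single-cell cohort with planted ground truth
#'
#' Draws a cells-by-genes negative-binomial count matrix under the design
#' in `config`: the NB mean of gene g in cell c is
#' `baseline[g] * fold_change(g, genotype[c], cell_type[c]) * size_factor[c]`,
#' with lognormal size factors. Spike-in counts are drawn from their own
#' means with no size factor and no planted effects, so they carry
#' technical noise only. The same `config` (including its seed) always
#' yields the identical cohort.
#'
#' @param config a [sim_config()].
#' @return list with
#' \describe{
#'   \item{sce}{`SingleCellExperiment` with assay `"counts"`,
#'     `rowData(sce)$spikein`, and colData `genotype`, `sample`,
#'     `cell_type` (the true type, which downstream annotation may
#'     overwrite).}
#'   \item{cell_truth}{data.frame: per-cell true type, genotype, size
#'     factor, one `active_<set>` flag per effect set, and `p53_active`.}
#'   \item{gene_effects}{the expanded effect table actually planted.}
#' }
#' @export
simulate_hspc_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  genes <- names(config$baseline_means)
  G <- length(genes)
  design <- config$n_cells_per_type
  cells <- do.call(rbind, lapply(rownames(design), function(g)
    do.call(rbind, lapply(colnames(design), function(ct)
      if (design[g, ct] > 0)
        data.frame(genotype = g, cell_type = ct,
                   stringsAsFactors = FALSE)[rep(1, design[g, ct]), ]
      else NULL))))
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  # two pseudo-samples per genotype, alternating cells
  cells$sample <- paste0(cells$genotype, "_s",
                         1L + (ave(seq_len(n_cells), cells$genotype,
                                   FUN = seq_along) %% 2L))

  eff <- config$effect_table
  # per (genotype, cell_type) log fold-change vector over genes
  fc_for <- function(g, ct) {
    lfc <- rep(0, G)
    if (nrow(eff)) {
      hit <- (eff$genotype == g | eff$genotype == "*") &
             (eff$cell_type == ct | eff$cell_type == "*")
      if (any(hit)) {
        idx <- match(eff$gene[hit], genes)
        lfc_add <- log(eff$fold_change[hit])
        for (i in seq_along(idx)) lfc[idx[i]] <- lfc[idx[i]] + lfc_add[i]
      }
    }
    exp(lfc)
  }

  with_local_seed(config$seed, {
    sf <- rlnorm(n_cells, 0, config$library_size_spread)
    combos <- unique(cells[c("genotype", "cell_type")])
    fc_list <- lapply(seq_len(nrow(combos)), function(i)
      fc_for(combos$genotype[i], combos$cell_type[i]))
    names(fc_list) <- paste(combos$genotype, combos$cell_type, sep = "\r")
    mu <- matrix(0, nrow = G, ncol = n_cells)
    key <- paste(cells$genotype, cells$cell_type, sep = "\r")
    for (j in seq_len(n_cells))
      mu[, j] <- config$baseline_means * fc_list[[key[j]]] * sf[j]
    counts <- matrix(rnbinom(G * n_cells, mu = as.vector(mu),
                             size = config$dispersion),
                     nrow = G, dimnames = list(genes, cells$cell_id))
    if (config$n_spikeins > 0) {
      smu <- rep_len(config$spikein_means, config$n_spikeins)
      spikes <- matrix(rnbinom(config$n_spikeins * n_cells,
                               mu = rep(smu, n_cells), size = 10),
                       nrow = config$n_spikeins,
                       dimnames = list(sprintf("ERCC-%05d",
                                               seq_len(config$n_spikeins)),
                                       cells$cell_id))
      counts <- rbind(counts, spikes)
    }
    counts
  }) -> counts

  spike <- c(rep(FALSE, G), rep(TRUE, config$n_spikeins))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(spikein = spike,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(cell_id = cells$cell_id,
                                   genotype = cells$genotype,
                                   sample = cells$sample,
                                   cell_type = cells$cell_type,
                                   row.names = cells$cell_id))

  truth <- cells[c("cell_id", "genotype", "cell_type")]
  sets <- unique(eff$set)
  for (s in sets) {
    sub <- eff[eff$set == s, ]
    truth[[paste0("active_", s)]] <- vapply(seq_len(n_cells), function(i)
      any((sub$genotype == cells$genotype[i] | sub$genotype == "*") &
          (sub$cell_type == cells$cell_type[i] | sub$cell_type == "*")),
      logical(1))
  }
  truth$p53_active <- if (paste0("active_", config$p53_set) %in% colnames(truth))
    truth[[paste0("active_", config$p53_set)]] else rep(FALSE, n_cells)

  list(sce = sce, cell_truth = truth, gene_effects = eff)
}

#' Simulate a survival cohort stratified by a score
#'
#' Event times are exponential; subjects in the "high" score group have
#' hazard `hr_high` times baseline. Censoring times are independent
#' exponentials with rate `censor_rate` times the baseline hazard
#' (`censor_rate = 0` disables censoring). Scores are standard normal
#' and the top `round(n * frac_high)` scores define the high group, so
#' group membership and score ordering agree by construction. Binary
#' covariates `age_gt60` and `prior_treatment` are drawn independently
#' of the score group.
#'
#' @param n number of subjects (>= 10).
#' @param hr_high hazard ratio of the high-score group (> 0).
#' @param frac_high fraction of subjects in the high group (0 < f < 1).
#' @param censor_rate censoring hazard as a multiple of baseline (>= 0).
#' @param seed integer seed.
#' @param baseline_median_days median survival of the low group, days.
#' @return data.frame: `subject_id`, `time_days`, `event` (TRUE = death),
#'   `group` ("high"/"low"), `score`, `age_gt60`, `prior_treatment`.
#' @export
simulate_survival_cohort <- function(n, hr_high = 2.34, frac_high = 0.25,
                                     censor_rate = 0.3, seed = 1L,
                                     baseline_median_days = 365) {
  if (length(n) != 1L || !is.finite(n) || n < 10)
    stop("'n' must be a single count >= 10")
  if (hr_high <= 0) stop("'hr_high' must be positive")
  if (frac_high <= 0 || frac_high >= 1)
    stop("'frac_high' must be strictly between 0 and 1")
  if (censor_rate < 0) stop("'censor_rate' must be >= 0")
  n <- as.integer(n)
  lambda0 <- log(2) / baseline_median_days
  with_local_seed(seed, {
    score <- rnorm(n)
    n_high <- as.integer(round(n * frac_high))
    high <- rank(-score, ties.method = "first") <= n_high
    tt <- rexp(n, rate = lambda0 * ifelse(high, hr_high, 1))
    cc <- if (censor_rate > 0) rexp(n, rate = lambda0 * censor_rate)
          else rep(Inf, n)
    data.frame(
      subject_id = sprintf("subj_%05d", seq_len(n)),
      time_days = pmin(tt, cc),
      event = tt <= cc,
      group = ifelse(high, "high", "low"),
      score = score,
      age_gt60 = rbinom(n, 1, 0.5),
      prior_treatment = rbinom(n, 1, 0.3),
      stringsAsFactors = FALSE)
  })
}

#' Write a simulated cohort to disk
#'
#' Serializes counts as Matrix Market MTX with `genes.tsv` /
#' `barcodes.tsv` sidecars plus `cellmeta.tsv` and `groundtruth.tsv`,
#' so tests and pipelines can reload the exact planted structure without
#' re-deriving it.
#'
#' @param cohort result of [simulate_hspc_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(cohort$sce, dir)
  write.table(cohort$cell_truth, file.path(dir, "groundtruth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$gene_effects, file.path(dir, "gene_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
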