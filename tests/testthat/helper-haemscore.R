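# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized implementations.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(SummarizedExperiment)
})

# area under the ROC curve via the rank-sum identity
auroc <- function(score, flag) {
  flag <- as.logical(flag)
  n1 <- sum(flag); n0 <- sum(!flag)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(score)
  (sum(r[flag]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# minimal SCE from a dense genes x cells matrix
make_sce <- function(counts, spikein = NULL, genotype = NULL,
                     cell_type = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  if (is.null(spikein)) spikein <- rep(FALSE, nrow(counts))
  cd <- S4Vectors::DataFrame(cell_id = colnames(counts),
                             row.names = colnames(counts))
  if (!is.null(genotype)) cd$genotype <- genotype
  if (!is.null(cell_type)) cd$cell_type <- cell_type
  SingleCellExperiment(assays = list(counts = counts),
                       rowData = S4Vectors::DataFrame(spikein = spikein),
                       colData = cd)
}

# straight-line reimplementation of bin-matched control scoring:
# rank genes by mean, cut into equal-size bins, sample controls per
# signature gene under the seed, de-duplicate, subtract control mean
oracle_bin_score <- function(m, sig_genes, n_bins, ctrl_per_gene, seed) {
  means <- apply(m, 1, mean)
  ord <- order(means, rownames(m))
  pos <- integer(nrow(m)); pos[ord] <- seq_len(nrow(m))
  bin <- ceiling(pos * n_bins / nrow(m))
  names(bin) <- rownames(m)
  set.seed(seed)
  picked <- character(0)
  for (g in sig_genes) {
    cand <- sort(names(bin)[bin == bin[[g]]])
    picked <- c(picked, sample(cand, min(ctrl_per_gene, length(cand))))
  }
  ctrl <- setdiff(unique(picked), sig_genes)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m)))
    out[j] <- mean(m[sig_genes, j]) - mean(m[ctrl, j])
  names(out) <- colnames(m)
  out
}

# product-limit estimator as an explicit loop over distinct times
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# cohort shared by several scoring tests: 25% of cells carry a 4x
# activation of the 16-gene p53 target set
p53_planted_cohort <- function(n_cells = 1000L, seed = 11L) {
  types <- c("HSPC" = "stem")
  n_act <- as.integer(n_cells * 0.25)
  design <- matrix(c(n_cells - n_act, n_act), nrow = 2, ncol = 1,
                   dimnames = list(c("WT", "DKO"), "HSPC"))
  genes <- c(haem_p53_genes,
             sprintf("Bg%04d", seq_len(500 - length(haem_p53_genes))))
  means <- with_seed_lognorm(length(genes), seed)
  names(means) <- genes
  means[haem_p53_genes] <- 2
  cfg <- sim_config(genotypes = c("WT", "DKO"), cell_types = types,
                    n_cells_per_type = design, baseline_means = means,
                    dispersion = 2,
                    effect_table = effect_entry("p53", haem_p53_genes,
                                                "DKO", "*", 4),
                    n_spikeins = 0L, library_size_spread = 0.3,
                    seed = seed)
  simulate_hspc_cohort(cfg)
}

with_seed_lognorm <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed + 7L)
  x <- rlnorm(n, log(0.8), 1.2)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  x
}

# log-normalized layers in one call
process_layers <- function(sce) scale_genes(log_transform(normalize_counts(sce)))

# builds a cohort whose biological variation lives in a known gene set:
# spike-ins and null genes are pure NB noise, 50 genes get an extra
# lognormal biological component (CV2_biol ~ 0.5)
hvg_fixture <- function(n_cells = 500L, n_null = 950L, n_var = 50L,
                        seed = 19L) {
  set.seed(seed)
  genes <- c(sprintf("var%03d", seq_len(n_var)),
             sprintf("null%03d", seq_len(n_null)))
  mu <- setNames(rlnorm(n_var + n_null, log(5), 0.8), genes)
  theta <- 10                      # modest technical overdispersion
  counts <- matrix(rnbinom((n_var + n_null) * n_cells,
                           mu = rep(mu, n_cells), size = theta),
                   nrow = n_var + n_null,
                   dimnames = list(genes, sprintf("c%04d", 1:n_cells)))
  # biological variation: per-cell lognormal factor with variance 0.5
  sig <- sqrt(log(1.5))            # lognormal CV2 = exp(sig^2) - 1 = 0.5
  for (i in seq_len(n_var)) {
    f <- rlnorm(n_cells, -sig^2 / 2, sig)
    counts[i, ] <- rnbinom(n_cells, mu = mu[i] * f, size = theta)
  }
  smu <- 2^seq(-2, 9, length.out = 92)
  spikes <- matrix(rnbinom(92 * n_cells, mu = rep(smu, n_cells), size = theta),
                   nrow = 92,
                   dimnames = list(sprintf("ERCC-%02d", 1:92),
                                   sprintf("c%04d", 1:n_cells)))
  make_sce(rbind(counts, spikes),
           spikein = c(rep(FALSE, n_var + n_null), rep(TRUE, 92)))
}
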