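test_that("rank-sum test matches exact enumeration on tiny samples", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)        # 2/20 orderings are at least this extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("large-sample rank-sum p agrees with the normal-approximation formula", {
  set.seed(61)
  x <- rnorm(80); y <- rnorm(90, 0.4)
  got <- rank_sum_test(x, y, "two.sided")
  # independent oracle: U statistic and tie-free normal approximation
  # with continuity correction, computed from first principles
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  sd_u <- sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  p <- 2 * pnorm((abs(U - mu) - 0.5) / sd_u, lower.tail = FALSE)
  expect_equal(got$statistic, U)
  expect_lt(abs(got$p - p) / p, 0.05)
})

# cohort with 16 truly p53-dependent genes (up in DKO, restored in TKO)
# and 20 decoys up in both DKO and TKO (not rescued)
dependence_cohort <- function(n_per = 100L, seed = 71L) {
  decoys <- sprintf("Decoy%02d", 1:20)
  base <- default_hspc_config(n_per_type = n_per, n_genes = 1000L,
                              seed = seed)
  cfg <- sim_config(
    genotypes = base$genotypes, cell_types = base$cell_types,
    n_cells_per_type = base$n_cells_per_type,
    baseline_means = c(base$baseline_means, setNames(rep(2, 20), decoys)),
    dispersion = 2,
    effect_table = rbind(base$effect_table,
                         effect_entry("decoy", decoys, "DKO", "*", 4),
                         effect_entry("decoy", decoys, "TKO", "*", 4)),
    n_spikeins = 92L, seed = seed)
  list(cfg = cfg, decoys = decoys)
}

test_that("dependence calling selects rescued genes and rejects decoys", {
  dc <- dependence_cohort()
  co <- simulate_hspc_cohort(dc$cfg)
  sce <- log_transform(normalize_counts(co$sce))
  calls <- identify_p53_dependent_genes(
    sce, candidates = c(haem_p53_genes, dc$decoys), min_types = 3)
  selected <- calls$gene[calls$selected]
  expect_setequal(selected, haem_p53_genes)
  expect_length(intersect(selected, dc$decoys), 0)
  # output sorted by dependent-type count, then symbol
  expect_true(!is.unsorted(rev(calls$n_dependent_types)))
})

test_that("identical expression across genotypes selects nothing", {
  set.seed(73)
  m <- matrix(rnbinom(50 * 180, mu = 3, size = 2), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:180)))
  meta <- data.frame(genotype = rep(c("WT", "DKO", "TKO"), each = 60),
                     cell_type = rep(rep(c("A", "B"), each = 30), 3))
  calls <- identify_p53_dependent_genes(m, meta, candidates = rownames(m),
                                        min_types = 1)
  expect_length(calls$gene[calls$selected], 0)
})

test_that("dependence selection is monotone in min_types", {
  dc <- dependence_cohort(n_per = 40L, seed = 79L)
  co <- simulate_hspc_cohort(dc$cfg)
  sce <- log_transform(normalize_counts(co$sce))
  prev <- Inf
  for (mt in 1:6) {
    calls <- identify_p53_dependent_genes(
      sce, candidates = c(haem_p53_genes, dc$decoys), min_types = mt)
    n_sel <- sum(calls$selected)
    expect_lte(n_sel, prev)
    prev <- n_sel
  }
})

test_that("missing genotypes and empty candidate overlaps raise errors", {
  m <- matrix(1, nrow = 5, ncol = 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  meta <- data.frame(genotype = rep("WT", 10), cell_type = rep("A", 10))
  expect_error(identify_p53_dependent_genes(m, meta, candidates = "g1"),
               "absent")
  meta$genotype <- rep(c("WT", "DKO", "TKO"), length.out = 10)
  expect_error(identify_p53_dependent_genes(m, meta, candidates = "nope"),
               "candidate")
})

test_that("under the global null the selected fraction stays near alpha", {
  # 200 replicates of exchangeable genotypes, min_types = 1
  set.seed(83)
  n_genes <- 20; n_per <- 20
  frac <- vapply(1:200, function(i) {
    m <- matrix(rnorm(n_genes * n_per * 3), nrow = n_genes)
    rownames(m) <- sprintf("g%02d", 1:n_genes)
    colnames(m) <- sprintf("c%02d", seq_len(n_per * 3))
    meta <- data.frame(genotype = rep(c("WT", "DKO", "TKO"), each = n_per),
                       cell_type = "A")
    calls <- identify_p53_dependent_genes(m, meta, candidates = rownames(m),
                                          min_types = 1, alpha = 0.05)
    mean(calls$selected)
  }, numeric(1))
  # both one-sided BH-adjusted contrasts must pass, so the null rate is
  # well below alpha; allow 2x the binomial sd above alpha
  expect_lte(mean(frac), 0.05 + 2 * sqrt(0.05 * 0.95 / (200 * n_genes)))
})

test_that("score-correlation ranking matches the covariance formula", {
  set.seed(89)
  n <- 50
  score <- rnorm(n)
  m <- matrix(rnorm(30 * n), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:n)))
  m[1, ] <- 2 + 3 * score              # perfectly correlated
  m[2, ] <- 1                          # constant
  res <- rank_score_correlated_genes(m, score)
  expect_equal(res$r[res$gene == "g01"], 1, tolerance = 1e-9)
  expect_equal(res$rank[res$gene == "g01"], 1L)
  expect_true(res$constant[res$gene == "g02"])
  expect_true(is.na(res$r[res$gene == "g02"]))
  # brute-force covariance-formula oracle for ordering
  r_oracle <- apply(m[-2, ], 1, function(v) {
    num <- sum((v - mean(v)) * (score - mean(score)))
    num / sqrt(sum((v - mean(v))^2) * sum((score - mean(score))^2))
  })
  want <- names(sort(r_oracle, decreasing = TRUE))
  expect_identical(res$gene[!res$constant], want)
  # affine transforms of the score leave r unchanged (up to sign)
  res2 <- rank_score_correlated_genes(m, 3 * score + 10)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  res3 <- rank_score_correlated_genes(m, -score)
  expect_equal(res3$r[match(res$gene, res3$gene)], -res$r, tolerance = 1e-12)
  expect_error(rank_score_correlated_genes(m[, 1:10], score[1:10]),
               "cells")
})

test_that("lineage proportions sum to one and recover planted fractions", {
  meta1 <- data.frame(genotype = "WT", cell_type = rep("GMP", 5))
  tab1 <- lineage_proportions(meta1, c(GMP = "myeloid"))
  expect_equal(tab1$by_type$proportion, 1.0)
  cfg <- default_hspc_config(n_per_type = 1L, n_genes = 320L, seed = 97L)
  design <- myeloid_biased_design(cfg$cell_types,
                                  n_per_genotype = c(WT = 500L, DKO = 500L),
                                  myeloid_frac = c(WT = 0.3, DKO = 0.6))
  meta <- do.call(rbind, lapply(rownames(design), function(g)
    do.call(rbind, lapply(colnames(design), function(ct)
      data.frame(genotype = rep(g, design[g, ct]), cell_type = ct)))))
  tab <- lineage_proportions(meta, cfg$cell_types)
  by_class <- tab$by_class
  expect_equal(by_class$proportion[by_class$genotype == "WT" &
                                   by_class$lineage == "myeloid"], 0.3)
  expect_equal(by_class$proportion[by_class$genotype == "DKO" &
                                   by_class$lineage == "myeloid"], 0.6)
  sums <- tapply(tab$by_type$proportion, tab$by_type$genotype, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(lineage_proportions(meta, c(GMP = "myeloid")), "lineage_map")
})

test_that("telomere differences pair by mouse id regardless of order", {
  hsc <- c(m1 = 5000, m2 = 4800)
  tail <- c(m2 = 5000, m1 = 5000)
  d <- telomere_difference(hsc, tail)
  expect_equal(unname(d), c(0, -200))
  expect_equal(d[["m2"]], -200)
  expect_error(telomere_difference(hsc, c(m1 = 1)), "unmatched")
  expect_error(telomere_difference(unname(hsc), tail), "named")
})
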