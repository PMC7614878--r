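test_that("packaged signatures carry the expected gene lists", {
  expect_length(aging_signature_genes, 20)
  expect_identical(aging_signature_genes[1], "Selp")
  expect_identical(aging_signature_genes[20], "Fhl1")
  expect_length(haem_p53_genes, 16)
  expect_identical(haem_p53_genes[1], "Cdkn1a")
  expect_identical(haem_p53_genes[16], "Pml")
  expect_false(anyDuplicated(haem_p53_genes) > 0)
})

test_that("uniform expression scores zero in both control modes", {
  m <- matrix(3, nrow = 100, ncol = 5,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%d", 1:5)))
  sig <- gene_signature("s", rownames(m)[1:10])
  expect_equal(unname(score_gene_set(m, sig, n_bins = 5, seed = 0)$score),
               rep(0, 5))
  sig_fix <- gene_signature("s", rownames(m)[1:10],
                            reference_pool = rownames(m)[11:40])
  expect_equal(unname(score_gene_set(m, sig_fix)$score), rep(0, 5))
})

test_that("fixed-pool score is the exact mean difference", {
  m <- matrix(1, nrow = 20, ncol = 3,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  m[1:5, ] <- 2
  sig <- gene_signature("s", rownames(m)[1:5],
                        reference_pool = rownames(m)[6:20])
  expect_equal(unname(score_gene_set(m, sig)$score), rep(1, 3))
})

test_that("bin-matched scoring equals the straight-line oracle", {
  set.seed(31)
  m <- matrix(rnorm(200 * 20), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:20)))
  sig_genes <- sample(rownames(m), 12)
  for (seed in c(0L, 1L, 99L)) {
    got <- score_gene_set(m, gene_signature("s", sig_genes),
                          n_bins = 5, ctrl_per_gene = 10, seed = seed)
    want <- oracle_bin_score(m, sig_genes, 5, 10, seed)
    expect_equal(got$score, want, tolerance = 1e-12)
    expect_length(setdiff(got$control_genes, rownames(m)), 0)
    expect_length(intersect(got$control_genes, sig_genes), 0)
  }
})

test_that("scores are deterministic in the seed and symmetric in gene order", {
  set.seed(5)
  m <- matrix(rnorm(150 * 10), nrow = 150,
              dimnames = list(sprintf("g%03d", 1:150), sprintf("c%02d", 1:10)))
  genes <- rownames(m)[21:36]
  a <- score_gene_set(m, gene_signature("s", genes), n_bins = 10, seed = 4)
  b <- score_gene_set(m, gene_signature("s", genes), n_bins = 10, seed = 4)
  expect_identical(a$score, b$score)
  c_ <- score_gene_set(m, gene_signature("s", rev(genes)), n_bins = 10,
                       seed = 4)
  expect_equal(a$score, c_$score, tolerance = 1e-9)
  # with few controls per gene, different seeds draw different controls
  d5 <- score_gene_set(m, gene_signature("s", genes), n_bins = 10,
                       ctrl_per_gene = 3, seed = 5)
  d6 <- score_gene_set(m, gene_signature("s", genes), n_bins = 10,
                       ctrl_per_gene = 3, seed = 6)
  expect_false(identical(d5$control_genes, d6$control_genes))
})

test_that("fixed-pool scores are shift invariant and monotone in signal", {
  set.seed(6)
  m <- matrix(abs(rnorm(60 * 8)) + 0.1, nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("c%d", 1:8)))
  sig <- gene_signature("s", rownames(m)[1:10],
                        reference_pool = rownames(m)[31:60])
  base <- score_gene_set(m, sig)$score
  shifted <- m; shifted[, 3] <- shifted[, 3] + 5   # shift one whole cell
  expect_equal(score_gene_set(shifted, sig)$score, base, tolerance = 1e-12)
  for (lambda in c(1.2, 1.5, 3)) {
    boosted <- m; boosted[1:10, 3] <- boosted[1:10, 3] * lambda
    expect_gt(score_gene_set(boosted, sig)$score[[3]], base[[3]])
  }
})

test_that("missing signature genes warn above half coverage and error below", {
  m <- matrix(rnorm(50 * 4), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%d", 1:4)))
  sig <- gene_signature("s", c(rownames(m)[1:6], "absent1", "absent2"))
  expect_warning(score_gene_set(m, sig, n_bins = 5, seed = 0), "renormalized")
  sig2 <- gene_signature("s", c(rownames(m)[1:3],
                                paste0("absent", 1:5)))
  expect_error(score_gene_set(m, sig2, n_bins = 5, seed = 0), "absent")
  expect_error(gene_signature("s", c("a", "b"), reference_pool = c("b", "c")),
               "overlaps")
})

test_that("aging score separates planted aged cells", {
  types <- c(A = "stem")
  design <- matrix(c(300L, 300L), nrow = 2,
                   dimnames = list(c("young", "aged"), "A"))
  genes <- c(aging_signature_genes, sprintf("bg%03d", 1:180))
  means <- setNames(rep(1.5, 200), genes)
  cfg <- sim_config(genotypes = c("young", "aged"), cell_types = types,
                    n_cells_per_type = design, baseline_means = means,
                    dispersion = 2,
                    effect_table = effect_entry("aging",
                                                aging_signature_genes,
                                                "aged", "*", 3),
                    n_spikeins = 0L, seed = 17L)
  co <- simulate_hspc_cohort(cfg)
  sce <- process_layers(co$sce)
  sc <- aging_signature_score(sce, seed = 0)
  aged <- co$cell_truth$genotype == "aged"
  expect_gt(mean(sc$score[aged]), mean(sc$score[!aged]))
  expect_gt(auroc(sc$score, aged), 0.9)
})

test_that("all-zero expression yields all-zero scores", {
  m <- matrix(0, nrow = 60, ncol = 4,
              dimnames = list(c(aging_signature_genes,
                                sprintf("bg%02d", 1:40)),
                              sprintf("c%d", 1:4)))
  sc <- score_gene_set(m, gene_signature("aging", aging_signature_genes),
                       n_bins = 5, seed = 0)
  expect_equal(unname(sc$score), rep(0, 4))
})

test_that("human symbol mapping uppercases with overrides", {
  expect_identical(map_symbols_to_human(c("Cdkn1a", "Trp53")),
                   c("CDKN1A", "TP53"))
  m <- matrix(rnorm(40 * 30), nrow = 40,
              dimnames = list(c(map_symbols_to_human(haem_p53_genes),
                                sprintf("BG%02d", 1:24)),
                              sprintf("c%02d", 1:30)))
  sc <- haem_p53_score(m, species = "human", n_bins = 4, seed = 0)
  expect_equal(sc$genes_used, 16)
})

test_that("cell-cycle phase follows the documented decision rule", {
  # build a matrix whose scores are controlled through fixed pools
  s_genes <- sprintf("s%02d", 1:5)
  g2m_genes <- sprintf("m%02d", 1:5)
  ref <- sprintf("r%02d", 1:20)
  m <- matrix(1, nrow = 30, ncol = 3,
              dimnames = list(c(s_genes, g2m_genes, ref), c("g1", "s", "g2m")))
  m[s_genes, "g1"] <- 0.8; m[g2m_genes, "g1"] <- 0.9      # both negative
  m[s_genes, "s"] <- 1.5; m[g2m_genes, "s"] <- 1.2        # S wins
  m[s_genes, "g2m"] <- 1.1; m[g2m_genes, "g2m"] <- 1.1    # tie -> G2M
  # emulate via direct scoring with fixed pools
  s_sig <- gene_signature("S", s_genes, reference_pool = ref)
  g_sig <- gene_signature("G2M", g2m_genes, reference_pool = ref)
  s <- score_gene_set(m, s_sig)$score
  g <- score_gene_set(m, g_sig)$score
  phase <- ifelse(s < 0 & g < 0, "G1", ifelse(g >= s, "G2M", "S"))
  expect_identical(unname(phase), c("G1", "S", "G2M"))
  # and the packaged rule agrees on simulated data
  co <- simulate_hspc_cohort(default_hspc_config(n_per_type = 6L,
                                                 n_genes = 320L, seed = 12L))
  sce <- process_layers(co$sce)
  res <- assign_cell_cycle_phase(sce, s_genes = haem_p53_genes[1:8],
                                 g2m_genes = aging_signature_genes[1:8],
                                 seed = 0)
  expect_true(all(res$phase %in% c("G1", "S", "G2M")))
  expect_identical(res$phase,
                   ifelse(res$s_score < 0 & res$g2m_score < 0, "G1",
                          ifelse(res$g2m_score >= res$s_score, "G2M", "S")))
  expect_error(assign_cell_cycle_phase(sce, s_genes = "nope",
                                       g2m_genes = "nada"), "intersect")
})
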