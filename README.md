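# haemscore

Signature scoring, reference-projection cell typing and survival
stratification for hematopoietic single-cell transcriptomics.

HSPCs (hematopoietic stem and progenitor cells) exposed to chronic DNA
damage show two coupled phenotypes: a transcriptome resembling that of
aged stem cells, and persistent p53 pathway activation that biases
output toward the myeloid lineage and, in leukemia, predicts worse
survival. `haemscore` provides the quantitative toolkit for this
analysis:

* **Control-referenced gene-set scores** — for cell *c* and signature
  *G*, `s_c = mean(x_gc, g in G) − mean(x_gc, g in C)` where the
  control set *C* is either expression-matched (genes binned by mean
  expression, seeded sampling per signature gene) or a fixed reference
  pool. Two signatures ship with the package: a 20-gene HSC **aging
  signature** (`aging_signature_genes`, *Selp* … *Fhl1*) and the
  16-gene **hematopoietic p53 score** (`haem_p53_genes`, *Cdkn1a* …
  *Pml*), plus cell-cycle phase assignment from S/G2M scores.
* **Processing** — cell QC, counts-per-10K normalization, log1p,
  gene scaling, covariate (e.g. cell-cycle) regression, Matrix Market
  I/O; all on `SingleCellExperiment`.
* **Reference projection** — Brennecke-style spike-in calibrated HVG
  selection (with a dispersion-based fallback), PCA reference
  landscapes, exact Euclidean 15-nearest-neighbor label transfer, and
  two-tier (key → refinement) hierarchical cell typing.
* **p53-dependence calling** — a gene is p53-dependent in a cell type
  when it is up in the damage mutant vs wild type *and* rescued
  (higher in mutant than in mutant with p53 deleted), by one-sided
  rank-sum tests with BH correction; selected when dependent in ≥ 3
  cell types. Plus score–gene correlation ranking and lineage
  composition tables.
* **Survival** — top-quantile score stratification, Kaplan–Meier
  curves, Mantel–Haenszel log-rank with O/E hazard ratio, and
  multivariate Cox (Breslow ties) via the `survival` package.
* **Simulation** — a negative-binomial cohort generator
  (`simulate_hspc_cohort`) with planted genotype/cell-type effects,
  ERCC-like spike-ins and serialized ground truth, and a survival
  cohort generator with a planted hazard ratio, so every claim above
  is testable end to end.

## Worked example

Simulate the default study design — wild type (WT), a DNA-damage
double knockout with activated p53 (DKO), and the same background with
p53 additionally deleted (TKO) — then score p53 activity and stratify
a survival cohort:

```r
library(haemscore)
library(SummarizedExperiment)

cfg    <- default_hspc_config(n_per_type = 50L, n_genes = 600L, seed = 1L)
cohort <- simulate_hspc_cohort(cfg)
sce <- qc_filter_cells(compute_cell_qc(cohort$sce),
                       qc_thresholds(min_genes = 100, max_pct_mito = 0.1))
#> stage=qc removed=0 criterion=min_genes
#> stage=qc removed=91 criterion=max_pct_mito
sce <- scale_genes(log_transform(normalize_counts(sce)))

p53 <- haem_p53_score(sce, seed = 1)
round(tapply(p53$score, colData(sce)$genotype, mean), 3)
#>    DKO    TKO     WT
#>  0.695 -0.390 -0.357
```

DKO cells carry a clearly elevated p53 score; deleting p53 (TKO)
collapses it back to the wild-type level — the rescue pattern that
defines the signature. The aging score behaves the same way
(DKO 0.261 vs WT −0.135 on this cohort). On the survival side:

```r
surv  <- simulate_survival_cohort(n = 1000, hr_high = 2.34,
                                  frac_high = 0.25, seed = 1)
strat <- stratify_top_quantile(setNames(surv$score, surv$subject_id),
                               q = 0.25)
lr <- logrank_test_hr(surv, strat$group)
#> log-rank HR = 2.22 (95% CI 1.82-2.69), p = 3.4e-26

surv$score_high <- as.integer(strat$group == "high")
cox_fit(surv, c("score_high", "age_gt60", "prior_treatment"))
#>              term    coef    hr ci_low ci_high     se        p
#> 1      score_high  0.8441 2.326  1.982    2.73 0.0815 4.12e-25
#> 2        age_gt60  0.0824 1.086  0.945    1.25 0.0709 2.45e-01
#> 3 prior_treatment -0.0421 0.959  0.826    1.11 0.0763 5.81e-01
```

The top-25% score group carries the planted ~2.3-fold hazard, and the
multivariate Cox fit keeps it as an independent predictor next to the
(null) age and prior-treatment covariates.

`run_pipeline(pipeline_config(...))` chains all stages (simulate/load →
QC → normalize → type → score → dependence → proportions → survival)
with a manifest, and `make_fixtures()` writes a deterministic
miniature dataset exercising all of them. See the methods vignette
(`vignettes/haemscore-methods.Rmd`) for the model, parameter defaults
and design decisions.

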