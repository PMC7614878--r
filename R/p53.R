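#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin, contract-stable wrapper over the standard test: the exact null
#' distribution is used for small samples (min(n, m) <= 8) without
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative "two.sided", "greater" (x tends larger) or "less".
#' @return list with `statistic` (the U statistic of `x`) and `p`.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Identify p53-dependent genes from genotype contrasts
#'
#' Implements the defining expression pattern of a p53-dependent gene:
#' within a given HSPC cell type the gene is (i) upregulated in the
#' DNA-damage mutant relative to wild type and (ii) rescued -- i.e.
#' higher in the mutant than in the mutant with p53 additionally
#' deleted. Both directional contrasts use one-sided rank-sum tests,
#' Benjamini-Hochberg adjusted across the candidate set within each
#' cell type and contrast. A gene is called dependent in a cell type
#' when both adjusted tests pass `alpha`, and selected overall when it
#' is dependent in at least `min_types` cell types.
#'
#' @param x `SingleCellExperiment` or genes x cells matrix of (log)
#'   expression.
#' @param meta data.frame with per-cell `genotype` and `cell_type`
#'   (taken from `colData` when `x` is an experiment and `meta` is
#'   NULL).
#' @param candidates candidate gene universe (e.g. validated p53
#'   transcriptional targets).
#' @param genotypes named character vector mapping the roles `wt`,
#'   `mutant`, `mutant_p53null` to genotype labels in `meta`.
#' @param cell_types cell types to stratify by (default: all present).
#' @param min_types minimum number of dependent cell types for overall
#'   selection.
#' @param alpha BH-adjusted significance level per contrast.
#' @param min_cells cell types with fewer cells than this in any
#'   genotype are skipped (with a warning) for that gene's tally.
#' @param layer layer to use when `x` is an experiment.
#' @return data.frame, one row per candidate present in the matrix:
#'   `gene`, `n_dependent_types`, `selected`, plus per-cell-type
#'   logical columns `dependent_<type>` and the minimum adjusted
#'   p-values `q_up_<type>`, `q_rescue_<type>`. Rows are sorted by
#'   `n_dependent_types` (descending), then gene symbol.
#' @export
identify_p53_dependent_genes <- function(x, meta = NULL, candidates,
                                         genotypes = c(wt = "WT",
                                                       mutant = "DKO",
                                                       mutant_p53null = "TKO"),
                                         cell_types = NULL,
                                         min_types = 3L, alpha = 0.05,
                                         min_cells = 5L,
                                         layer = "logcounts") {
  if (!length(candidates)) stop("'candidates' must be non-empty")
  if (!all(c("wt", "mutant", "mutant_p53null") %in% names(genotypes)))
    stop("'genotypes' must name roles wt, mutant and mutant_p53null")
  if (methods::is(x, "SingleCellExperiment")) {
    if (is.null(meta))
      meta <- as.data.frame(SummarizedExperiment::colData(x))
    m <- as.matrix(.get_layer(x, layer))
  } else m <- as.matrix(x)
  if (!all(c("genotype", "cell_type") %in% colnames(meta)))
    stop("'meta' needs columns genotype and cell_type")
  if (nrow(meta) != ncol(m)) stop("'meta' must have one row per cell")
  absent <- setdiff(genotypes, unique(meta$genotype))
  if (length(absent))
    stop("genotype(s) absent from metadata: ", paste(absent, collapse = ", "))
  if (is.null(cell_types)) cell_types <- sort(unique(meta$cell_type))
  genes <- intersect(candidates, rownames(m))
  if (!length(genes)) stop("no candidate genes present in the matrix")

  dep <- matrix(FALSE, nrow = length(genes), ncol = length(cell_types),
                dimnames = list(genes, cell_types))
  q_up <- q_rs <- matrix(NA_real_, nrow = length(genes),
                         ncol = length(cell_types),
                         dimnames = list(genes, cell_types))
  for (ct in cell_types) {
    i_wt <- meta$cell_type == ct & meta$genotype == genotypes[["wt"]]
    i_mu <- meta$cell_type == ct & meta$genotype == genotypes[["mutant"]]
    i_nl <- meta$cell_type == ct & meta$genotype == genotypes[["mutant_p53null"]]
    if (min(sum(i_wt), sum(i_mu), sum(i_nl)) < min_cells) {
      warning(sprintf("cell type '%s' has < %d cells in a genotype; skipped",
                      ct, min_cells))
      next
    }
    p_up <- vapply(genes, function(g)
      rank_sum_test(m[g, i_mu], m[g, i_wt], "greater")$p, numeric(1))
    p_rs <- vapply(genes, function(g)
      rank_sum_test(m[g, i_mu], m[g, i_nl], "greater")$p, numeric(1))
    q_up[, ct] <- stats::p.adjust(p_up, "BH")
    q_rs[, ct] <- stats::p.adjust(p_rs, "BH")
    dep[, ct] <- q_up[, ct] < alpha & q_rs[, ct] < alpha
  }
  n_dep <- rowSums(dep)
  out <- data.frame(gene = genes, n_dependent_types = n_dep,
                    selected = n_dep >= min_types,
                    stringsAsFactors = FALSE)
  for (ct in cell_types) {
    out[[paste0("dependent_", ct)]] <- dep[, ct]
    out[[paste0("q_up_", ct)]] <- q_up[, ct]
    out[[paste0("q_rescue_", ct)]] <- q_rs[, ct]
  }
  out[order(-out$n_dependent_types, out$gene), , drop = FALSE]
}

#' Rank genes by Pearson correlation with a per-cell score
#'
#' Correlates every gene's expression with the given score across
#' cells. Constant genes have undefined correlation: they are reported
#' with `r = NA`, flagged, and excluded from the ranking. Finite
#' correlations are sorted descending, ties broken by gene symbol.
#'
#' @param x `SingleCellExperiment` or genes x cells matrix.
#' @param scores per-cell numeric score (e.g. the Haem p53Score).
#' @param min_cells minimum number of cells required.
#' @param layer layer to use when `x` is an experiment.
#' @return data.frame: `gene`, `r`, `rank` (NA for constant genes),
#'   `constant`.
#' @export
rank_score_correlated_genes <- function(x, scores, min_cells = 20L,
                                        layer = "logcounts") {
  m <- if (methods::is(x, "SingleCellExperiment"))
    as.matrix(.get_layer(x, layer)) else as.matrix(x)
  if (ncol(m) < min_cells)
    stop(sprintf("need at least %d cells, got %d", min_cells, ncol(m)))
  if (length(scores) != ncol(m))
    stop("'scores' must have one value per cell")
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  r <- rep(NA_real_, nrow(m))
  if (any(!constant))
    r[!constant] <- as.vector(stats::cor(t(m[!constant, , drop = FALSE]),
                                         scores))
  out <- data.frame(gene = rownames(m), r = r, constant = constant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$constant, -ifelse(is.na(out$r), -Inf, out$r),
                   out$gene), ]
  out$rank <- NA_integer_
  out$rank[!out$constant] <- seq_len(sum(!out$constant))
  rownames(out) <- NULL
  out
}

#' Lineage composition per genotype
#'
#' Counts cells per (genotype, cell type), converts them to
#' within-genotype proportions, and rolls the proportions up to lineage
#' classes (myeloid / lymphoid / stem). A genotype with zero cells is
#' reported as an explicit empty row rather than dividing by zero.
#'
#' @param meta data.frame (or `colData`) with `genotype` and
#'   `cell_type` per cell.
#' @param lineage_map named character vector: cell type -> lineage
#'   class; must cover every assigned cell type.
#' @return list with `by_type` (genotype, cell_type, n, proportion) and
#'   `by_class` (genotype, lineage class, n, proportion).
#' @export
lineage_proportions <- function(meta, lineage_map) {
  meta <- as.data.frame(meta)
  if (!all(c("genotype", "cell_type") %in% colnames(meta)))
    stop("'meta' needs columns genotype and cell_type")
  unmapped <- setdiff(unique(meta$cell_type), names(lineage_map))
  if (length(unmapped))
    stop("cell type(s) missing from lineage_map: ",
         paste(unmapped, collapse = ", "))
  genotypes <- unique(meta$genotype)
  types <- names(lineage_map)
  by_type <- expand.grid(genotype = genotypes, cell_type = types,
                         stringsAsFactors = FALSE)
  by_type$n <- mapply(function(g, ct)
    sum(meta$genotype == g & meta$cell_type == ct),
    by_type$genotype, by_type$cell_type)
  tot <- tapply(by_type$n, by_type$genotype, sum)[by_type$genotype]
  by_type$proportion <- ifelse(tot > 0, by_type$n / tot, NA_real_)
  by_type$lineage <- unname(lineage_map[by_type$cell_type])
  by_class <- stats::aggregate(n ~ genotype + lineage, by_type, sum)
  tot2 <- tapply(by_class$n, by_class$genotype, sum)[by_class$genotype]
  by_class$proportion <- ifelse(tot2 > 0, by_class$n / tot2, NA_real_)
  list(by_type = by_type[order(by_type$genotype, by_type$cell_type), ],
       by_class = by_class[order(by_class$genotype, by_class$lineage), ])
}

#' Paired telomere-length difference
#'
#' Difference between stem-cell and tail telomere length per mouse,
#' paired by id (HSC minus tail), robust to input ordering.
#'
#' @param hsc_lengths named numeric: telomere length of sorted LT-HSCs
#'   per mouse id.
#' @param tail_lengths named numeric: paired tail-sample lengths.
#' @return named numeric of per-mouse differences, in `hsc_lengths`
#'   order.
#' @export
telomere_difference <- function(hsc_lengths, tail_lengths) {
  if (is.null(names(hsc_lengths)) || is.null(names(tail_lengths)))
    stop("both inputs must be named by mouse id")
  missing <- setdiff(names(hsc_lengths), names(tail_lengths))
  if (length(missing))
    stop("unmatched mouse id(s): ", paste(missing, collapse = ", "))
  hsc_lengths - tail_lengths[names(hsc_lengths)]
}
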