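#' The 20-gene HSC aging signature
#'
#' Genes most consistently upregulated in aged versus young murine
#' long-term HSCs, used by [aging_signature_score()].
#' @format character vector of 20 mouse gene symbols.
#' @export
aging_signature_genes <- c(
  "Selp", "Mt1", "Nupr1", "Plscr2", "Clec1a", "Gstm2", "Enpp5", "Itgb3",
  "Mt2", "Clca3a1", "Zg16", "Sbspon", "Trpc1", "Gpr183", "Klhl4", "Ptprk",
  "Vwf", "Cd38", "Neo1", "Fhl1")

#' The 16-gene hematopoietic p53-target signature
#'
#' p53 transcriptional targets whose expression is p53-dependent across
#' multiple HSPC subtypes; the gene set behind [haem_p53_score()].
#' @format character vector of 16 mouse gene symbols.
#' @export
haem_p53_genes <- c(
  "Cdkn1a", "Eda2r", "Phlda3", "Bax", "Zmat3", "Pvt1", "Sulf2", "Ccng1",
  "Bbc3", "Perp", "Casp1", "Aen", "Tnfrsf10b", "Ctsd", "Ier5", "Pml")

#' Construct a gene signature
#'
#' @param name signature name.
#' @param genes character vector of unique gene symbols (non-empty).
#' @param reference_pool optional fixed control gene set; must be
#'   disjoint from `genes`. When set, scoring subtracts the mean over
#'   this pool instead of sampling expression-matched controls.
#' @param notes free-text annotation.
#' @return a `gene_signature` list.
#' @export
gene_signature <- function(name, genes, reference_pool = NULL, notes = "") {
  genes <- as.character(genes)
  if (!length(genes) || anyDuplicated(genes) || any(!nzchar(genes)))
    stop("'genes' must be a non-empty vector of unique, non-empty symbols")
  if (!is.null(reference_pool)) {
    reference_pool <- unique(as.character(reference_pool))
    overlap <- intersect(reference_pool, genes)
    if (length(overlap))
      stop("reference_pool overlaps the signature: ",
           paste(head(overlap, 5), collapse = ", "))
  }
  structure(list(name = name, genes = genes,
                 reference_pool = reference_pool, notes = notes),
            class = "gene_signature")
}

#' Map mouse gene symbols to human
#'
#' Uppercases symbols (Cdkn1a -> CDKN1A), with an override table for
#' known nomenclature divergences, so mouse-derived signatures can be
#' applied to human expression matrices.
#'
#' @param genes character vector of mouse symbols.
#' @param overrides named character vector: mouse symbol -> human symbol.
#' @return character vector of human symbols.
#' @export
map_symbols_to_human <- function(genes, overrides = c(Trp53 = "TP53")) {
  out <- toupper(genes)
  hit <- genes %in% names(overrides)
  out[hit] <- overrides[genes[hit]]
  out
}

.score_layer <- function(x, layer) {
  if (methods::is(x, "SingleCellExperiment")) {
    m <- as.matrix(.get_layer(x, layer))
    m[!spikein_mask(x), , drop = FALSE]
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
    m
  }
}

#' Control-referenced gene-set score
#'
#' The package's central statistic: for each cell, the mean expression
#' of the signature genes minus the mean expression of a control gene
#' set. Controls are either the signature's fixed `reference_pool`, or
#' sampled to match the signature's expression profile: all genes are
#' ranked by mean expression across cells, cut into `n_bins` equal-size
#' bins, and `ctrl_per_gene` control genes are drawn (seeded, without
#' replacement) from the bin of each signature gene; the union is
#' de-duplicated and signature genes are excluded from it. Identical
#' `(layer, signature, seed)` always give identical scores.
#'
#' Genes missing from the matrix are dropped with a warning while at
#' least half the signature is present (the score renormalizes over the
#' genes found); below that the call errors, because a half-empty
#' signature is no longer comparable across datasets.
#'
#' @param x `SingleCellExperiment`, or a genes x cells numeric matrix.
#' @param sig a [gene_signature()].
#' @param layer which layer to score when `x` is an experiment; the
#'   default `"scaled"` matches the convention of scoring z-scored log
#'   expression, `"logcounts"` scores raw log values.
#' @param n_bins number of expression bins for control matching.
#' @param ctrl_per_gene control genes sampled per signature gene.
#' @param seed integer seed for control sampling.
#' @return a `score_result`: list with `score` (named per-cell numeric),
#'   `genes_used`, `genes_missing`, `control_genes`, `seed`, `name`.
#' @export
score_gene_set <- function(x, sig, layer = "scaled", n_bins = 25L,
                           ctrl_per_gene = 50L, seed = 0L) {
  if (!inherits(sig, "gene_signature")) stop("'sig' must be a gene_signature")
  m <- .score_layer(x, layer)
  present <- intersect(sig$genes, rownames(m))
  missing <- setdiff(sig$genes, rownames(m))
  if (length(present) < length(sig$genes) / 2)
    stop(sprintf("only %d/%d signature genes present; missing: %s",
                 length(present), length(sig$genes),
                 paste(missing, collapse = ", ")))
  if (length(missing))
    warning(sprintf("signature '%s': %d gene(s) absent, score renormalized: %s",
                    sig$name, length(missing),
                    paste(missing, collapse = ", ")))
  sig_mean <- colMeans(m[present, , drop = FALSE])

  if (!is.null(sig$reference_pool)) {
    pool <- intersect(sig$reference_pool, rownames(m))
    if (!length(pool)) stop("no reference_pool genes present in the matrix")
    ctrl <- pool
  } else {
    if (n_bins < 1L || ctrl_per_gene < 1L)
      stop("'n_bins' and 'ctrl_per_gene' must be positive")
    means <- rowMeans(m)
    ord <- order(means, rownames(m))       # deterministic under ties
    pos <- integer(nrow(m)); pos[ord] <- seq_len(nrow(m))
    bin <- ceiling(pos * n_bins / nrow(m))
    names(bin) <- rownames(m)
    ctrl <- with_local_seed(seed, {
      picked <- character(0)
      for (g in present) {
        cand <- sort(names(bin)[bin == bin[[g]]])
        k <- min(ctrl_per_gene, length(cand))
        picked <- c(picked, sample(cand, k))
      }
      setdiff(unique(picked), sig$genes)
    })
    if (!length(ctrl)) stop("control sampling produced no genes")
  }
  ctrl_mean <- colMeans(m[ctrl, , drop = FALSE])
  structure(list(name = sig$name,
                 score = sig_mean - ctrl_mean,
                 genes_used = length(present),
                 genes_missing = missing,
                 control_genes = sort(ctrl),
                 seed = as.integer(seed)),
            class = "score_result")
}

#' HSC aging signature score
#'
#' [score_gene_set()] with the packaged 20-gene aging signature
#' ([aging_signature_genes]); higher scores indicate a transcriptome
#' closer to that of aged long-term HSCs.
#'
#' @inheritParams score_gene_set
#' @param ... passed to [score_gene_set()].
#' @return a `score_result`.
#' @export
aging_signature_score <- function(x, layer = "scaled", seed = 0L, ...) {
  score_gene_set(x, gene_signature("aging_signature", aging_signature_genes),
                 layer = layer, seed = seed, ...)
}

#' Hematopoietic p53 score (Haem p53Score)
#'
#' [score_gene_set()] with the packaged 16-gene p53-target signature
#' ([haem_p53_genes]); quantifies p53 transcriptional activity per cell.
#' For human matrices the mouse symbols are case-mapped via
#' [map_symbols_to_human()]. A fixed 694-gene style reference pool may
#' be supplied to reproduce fixed-control scoring; otherwise controls
#' are expression-matched and sampled.
#'
#' @inheritParams score_gene_set
#' @param reference_pool optional fixed control gene set.
#' @param species `"mouse"` (default) or `"human"`.
#' @param ... passed to [score_gene_set()].
#' @return a `score_result`.
#' @export
haem_p53_score <- function(x, layer = "scaled", reference_pool = NULL,
                           species = c("mouse", "human"), seed = 0L, ...) {
  species <- match.arg(species)
  genes <- if (species == "human") map_symbols_to_human(haem_p53_genes)
           else haem_p53_genes
  score_gene_set(x, gene_signature("haem_p53", genes,
                                   reference_pool = reference_pool),
                 layer = layer, seed = seed, ...)
}

#' Assign cell-cycle phases from S and G2/M scores
#'
#' Scores the S-phase and G2/M gene lists with [score_gene_set()]; a
#' cell is called G1 when both scores are negative, otherwise it takes
#' the label of the larger score, with exact ties resolved to G2M (a
#' fixed, documented tie-break).
#'
#' @inheritParams score_gene_set
#' @param s_genes,g2m_genes character vectors of phase marker genes;
#'   each must intersect the matrix.
#' @return data.frame with columns `phase` ("G1"/"S"/"G2M"), `s_score`,
#'   `g2m_score`, one row per cell.
#' @export
assign_cell_cycle_phase <- function(x, s_genes, g2m_genes, layer = "scaled",
                                    n_bins = 25L, ctrl_per_gene = 50L,
                                    seed = 0L) {
  m <- .score_layer(x, layer)
  if (!length(intersect(s_genes, rownames(m))) ||
      !length(intersect(g2m_genes, rownames(m))))
    stop("phase gene lists must intersect the expression matrix")
  s <- score_gene_set(x, gene_signature("s_phase", s_genes), layer = layer,
                      n_bins = n_bins, ctrl_per_gene = ctrl_per_gene,
                      seed = seed)$score
  g2m <- score_gene_set(x, gene_signature("g2m_phase", g2m_genes),
                        layer = layer, n_bins = n_bins,
                        ctrl_per_gene = ctrl_per_gene, seed = seed)$score
  phase <- ifelse(s < 0 & g2m < 0, "G1", ifelse(g2m >= s, "G2M", "S"))
  data.frame(phase = phase, s_score = s, g2m_score = g2m,
             row.names = colnames(m), stringsAsFactors = FALSE)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result '%s'>\n", x$name))
  cat(sprintf("  cells: %d  genes used: %d  missing: %d  controls: %d\n",
              length(x$score), x$genes_used, length(x$genes_missing),
              length(x$control_genes)))
  cat(sprintf("  score range: [%.3f, %.3f]\n", min(x$score), max(x$score)))
  invisible(x)
}
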