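#' Per-cell QC statistics
#'
#' Computes, from raw counts, the per-cell metrics the QC filter uses:
#' `n_genes_detected` and `total_counts` over biological genes,
#' `pct_mito` (fraction of biological counts on `mt-`/`MT-` genes) and
#' `pct_spikein` (spike-in counts over all counts). Results are written
#' into `colData`.
#'
#' @param x `SingleCellExperiment` with a `"counts"` assay.
#' @return `x` with QC columns added to `colData`.
#' @export
compute_cell_qc <- function(x) {
  counts <- .get_layer(x, "counts")
  spike <- spikein_mask(x)
  bio <- counts[!spike, , drop = FALSE]
  mito <- grepl("^mt-", rownames(bio), ignore.case = TRUE)
  total_bio <- Matrix::colSums(bio)
  total_all <- Matrix::colSums(counts)
  cd <- SummarizedExperiment::colData(x)
  cd$n_genes_detected <- Matrix::colSums(bio > 0)
  cd$total_counts <- total_bio
  cd$pct_mito <- ifelse(total_bio > 0,
                        Matrix::colSums(bio[mito, , drop = FALSE]) / total_bio,
                        0)
  cd$pct_spikein <- ifelse(total_all > 0,
                           Matrix::colSums(counts[spike, , drop = FALSE]) /
                             total_all, 0)
  SummarizedExperiment::colData(x) <- cd
  x
}

#' QC thresholds
#'
#' Boundary semantics follow the convention of the single-cell stack the
#' defaults come from: `min_*` are inclusive (a cell at exactly
#' `min_genes` is kept) and `max_*` remove cells strictly above the
#' threshold. `NULL` disables a criterion.
#'
#' @param min_genes minimum genes detected (inclusive).
#' @param max_pct_mito maximum mitochondrial fraction (cells above are
#'   removed).
#' @param min_total minimum total biological counts (inclusive); exposed
#'   per-sample-configurable read floors default to 100,000 for
#'   plate-based data when set.
#' @param max_pct_spikein maximum spike-in fraction.
#' @param max_total optional maximum total counts.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = NULL, max_pct_mito = NULL,
                          min_total = NULL, max_pct_spikein = NULL,
                          max_total = NULL) {
  if (!is.null(min_total) && !is.null(max_total) && min_total >= max_total)
    stop("'min_total' must be smaller than 'max_total'")
  structure(list(min_genes = min_genes, max_pct_mito = max_pct_mito,
                 min_total = min_total, max_pct_spikein = max_pct_spikein,
                 max_total = max_total),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Applies every set threshold of `t` and keeps cells passing all of
#' them; cell order is preserved and a structured log line per criterion
#' (`stage=qc removed=<n> criterion=<name>`) reports how many cells each
#' one removed (counted independently).
#'
#' @param x `SingleCellExperiment`; QC columns are computed on the fly
#'   when absent.
#' @param t a [qc_thresholds()].
#' @param verbose emit log lines via `message()`.
#' @return filtered `SingleCellExperiment`; the removal log is attached
#'   as `metadata(x)$qc_log`.
#' @export
qc_filter_cells <- function(x, t = qc_thresholds(), verbose = TRUE) {
  if (!inherits(t, "qc_thresholds")) stop("'t' must be qc_thresholds()")
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("n_genes_detected", "total_counts", "pct_mito",
             "pct_spikein") %in% colnames(cd))) {
    x <- compute_cell_qc(x)
    cd <- SummarizedExperiment::colData(x)
  }
  keep <- rep(TRUE, ncol(x))
  log <- data.frame(criterion = character(), removed = integer())
  apply_crit <- function(name, pass) {
    removed <- sum(!pass)
    log <<- rbind(log, data.frame(criterion = name, removed = removed))
    if (verbose)
      message(sprintf("stage=qc removed=%d criterion=%s", removed, name))
    keep <<- keep & pass
  }
  if (!is.null(t$min_genes))
    apply_crit("min_genes", cd$n_genes_detected >= t$min_genes)
  if (!is.null(t$max_pct_mito))
    apply_crit("max_pct_mito", cd$pct_mito <= t$max_pct_mito)
  if (!is.null(t$min_total))
    apply_crit("min_total", cd$total_counts >= t$min_total)
  if (!is.null(t$max_pct_spikein))
    apply_crit("max_pct_spikein", cd$pct_spikein <= t$max_pct_spikein)
  if (!is.null(t$max_total))
    apply_crit("max_total", cd$total_counts <= t$max_total)
  if (!any(keep)) {
    worst <- log$criterion[which.max(log$removed)]
    stop("QC removed every cell; binding criterion: ", worst)
  }
  out <- x[, keep]
  S4Vectors::metadata(out)$qc_log <- log
  out
}

#' Total-count normalization to a fixed target
#'
#' Rescales each cell so its biological genes sum to `target_sum`
#' (default 10,000); spike-ins are excluded from the denominator but
#' rescaled by the same per-cell factor. The result is stored as layer
#' `"norm10k"`. Idempotent on its own output.
#'
#' @param x `SingleCellExperiment` with a `"counts"` assay (or the layer
#'   named by `from`).
#' @param target_sum positive target total per cell.
#' @param from source layer name.
#' @return `x` with assay `"norm10k"` added.
#' @export
normalize_counts <- function(x, target_sum = 10000, from = "counts") {
  if (target_sum <= 0) stop("'target_sum' must be positive")
  m <- .get_layer(x, from)
  spike <- spikein_mask(x)
  totals <- Matrix::colSums(m[!spike, , drop = FALSE])
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0][1]
    stop("cell '", bad, "' has zero biological counts; run qc_filter_cells ",
         "before normalizing")
  }
  fac <- target_sum / totals
  norm <- as.matrix(m) %*% diag(fac, length(fac))
  dimnames(norm) <- dimnames(m)
  SummarizedExperiment::assay(x, "norm10k") <- norm
  x
}

#' Natural-log transform with pseudocount 1
#'
#' `log(value + 1)` elementwise; stored as layer `"logcounts"`.
#'
#' @param x `SingleCellExperiment`.
#' @param from source layer (default `"norm10k"`).
#' @return `x` with assay `"logcounts"` added.
#' @export
log_transform <- function(x, from = "norm10k") {
  m <- .get_layer(x, from)
  if (min(m) < 0) stop("log transform requires non-negative input")
  SummarizedExperiment::assay(x, "logcounts") <- log1p(as.matrix(m))
  x
}

#' Scale genes to zero mean and unit variance
#'
#' Standardizes each gene across cells using the population standard
#' deviation (divisor n, the convention of the single-cell stack);
#' zero-variance genes become all-zero rows rather than NaN. Stored as
#' layer `"scaled"`.
#'
#' @param x `SingleCellExperiment` (needs >= 2 cells).
#' @param from source layer (default `"logcounts"`).
#' @return `x` with assay `"scaled"` added.
#' @export
scale_genes <- function(x, from = "logcounts") {
  m <- as.matrix(.get_layer(x, from))
  if (ncol(m) < 2L) stop("scaling requires at least two cells")
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  s[s == 0 | !is.finite(s)] <- Inf  # constant genes -> zeros
  SummarizedExperiment::assay(x, "scaled") <- (m - mu) / s
  x
}

#' Regress covariates out of an expression layer
#'
#' Per gene, replaces expression with the residuals of an ordinary
#' least-squares fit on the given covariates (plus intercept).
#' Categorical covariates are expanded to indicators. Residuals are
#' orthogonal to every design column; a gene exactly linear in the
#' covariates becomes all-zero. Typically used to remove cell-cycle
#' phase effects before visualization or scoring.
#'
#' @param x `SingleCellExperiment`.
#' @param covariates character vector of `colData` columns, or a
#'   data.frame with one row per cell.
#' @param from source layer.
#' @param to output layer name (default overwrites `from`).
#' @return `x` with the residual layer.
#' @export
regress_out_covariates <- function(x, covariates, from = "logcounts",
                                   to = from) {
  m <- as.matrix(.get_layer(x, from))
  if (is.character(covariates)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    missing <- setdiff(covariates, colnames(cd))
    if (length(missing))
      stop("covariates absent from colData: ", paste(missing, collapse = ", "))
    covariates <- cd[covariates]
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(m))
    stop("covariate rows must match the number of cells")
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qrX, t(m)))
  dimnames(resid) <- dimnames(m)
  SummarizedExperiment::assay(x, to) <- resid
  x
}
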