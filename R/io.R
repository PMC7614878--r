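#' Read a cell-by-gene count matrix with sidecar metadata
#'
#' Supports the two on-disk forms used throughout the package:
#' \describe{
#'   \item{MTX triplet}{a directory holding `matrix.mtx` (genes x cells,
#'     1-based Matrix Market coordinates per the standard), `genes.tsv`
#'     (one symbol per line, optional second column `spikein` with
#'     TRUE/FALSE), `barcodes.tsv` (one cell id per line) and an optional
#'     `cellmeta.tsv` (tab-separated, mandatory columns `cell_id`,
#'     `genotype`).}
#'   \item{dense CSV}{a single file whose header row names the genes and
#'     whose first column holds cell ids (cells x genes); transposed on
#'     read.}
#' }
#' Spike-in rows are recognized from the `spikein` sidecar column or,
#' failing that, from an `ERCC` name prefix.
#'
#' @param path directory (MTX form) or `.csv` file (dense form).
#' @return `SingleCellExperiment` with assay `"counts"`.
#' @export
read_matrix <- function(path) {
  if (dir.exists(path)) .read_mtx_dir(path) else .read_dense_csv(path)
}

.read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  gfile <- file.path(dir, "genes.tsv")
  bfile <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, gfile, bfile))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- read.delim(gfile, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(bfile)
  if (nrow(genes) != nrow(m))
    stop(sprintf("matrix.mtx declares %d genes but genes.tsv has %d lines",
                 nrow(m), nrow(genes)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("matrix.mtx declares %d cells but barcodes.tsv has %d lines",
                 ncol(m), length(barcodes)))
  if (anyDuplicated(genes[[1]])) stop("gene identifiers must be unique")
  rownames(m) <- genes[[1]]
  colnames(m) <- barcodes
  spike <- if (ncol(genes) >= 2) as.logical(genes[[2]])
           else startsWith(genes[[1]], "ERCC")
  cd <- S4Vectors::DataFrame(cell_id = barcodes, row.names = barcodes)
  mfile <- file.path(dir, "cellmeta.tsv")
  if (file.exists(mfile)) {
    meta <- read.delim(mfile, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "genotype") %in% colnames(meta)))
      stop("cellmeta.tsv requires columns cell_id and genotype")
    idx <- match(barcodes, meta$cell_id)
    if (anyNA(idx)) stop("cellmeta.tsv is missing cells: ",
                         paste(head(barcodes[is.na(idx)], 5), collapse = ", "))
    cd <- S4Vectors::DataFrame(meta[idx, , drop = FALSE],
                               row.names = barcodes)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(spikein = spike, row.names = genes[[1]]),
    colData = cd)
}

.read_dense_csv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cells <- df[[1]]
  m <- t(as.matrix(df[-1]))  # to genes x cells
  colnames(m) <- cells
  if (anyDuplicated(rownames(m))) stop("gene identifiers must be unique")
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(spikein = startsWith(rownames(m), "ERCC"),
                                   row.names = rownames(m)),
    colData = S4Vectors::DataFrame(cell_id = cells, row.names = cells))
}

#' Write counts and cell metadata as an MTX triplet
#'
#' Inverse of [read_matrix()]: writes `matrix.mtx`, `genes.tsv` (symbol +
#' spike-in flag), `barcodes.tsv` and `cellmeta.tsv` so that
#' `read_matrix(write_matrix(x, dir))` round-trips counts and metadata.
#'
#' @param x `SingleCellExperiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(x, dir) {
  .assert_sce(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(SummarizedExperiment::assay(x, "counts"),
                               "sparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene = rownames(x), spikein = spikein_mask(x)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!"cell_id" %in% colnames(cd)) cd$cell_id <- colnames(x)
  write.table(cd, file.path(dir, "cellmeta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a gene signature from a plain-text or CSV file
#'
#' Accepts one symbol per line, or a two-column CSV `set,gene` where
#' `set` is either the signature name or the literal `reference` for
#' fixed control-pool genes.
#'
#' @param path input file.
#' @param name signature name (defaults to the file stem).
#' @return a [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("signature CSV needs columns set,gene")
    ref <- df[[2]][df[[1]] == "reference"]
    genes <- df[[2]][df[[1]] != "reference"]
    gene_signature(name, genes, reference_pool = if (length(ref)) ref else NULL)
  } else {
    gene_signature(name, trimws(readLines(path)))
  }
}
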