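#' Build a reference landscape for PCA projection
#'
#' Computes the PCA basis of an annotated reference: the log-expression
#' of the chosen highly variable genes is centered gene-wise and
#' decomposed by SVD; the top `n_components` right-singular vectors
#' (orthonormal loadings), the centering means, the reference cell
#' coordinates and the per-cell type labels together define the
#' landscape that queries are projected onto.
#'
#' @param ref `SingleCellExperiment` or genes x cells matrix of log
#'   expression.
#' @param labels character vector of cell-type labels, one per
#'   reference cell.
#' @param hvgs character vector of highly variable genes to build the
#'   space from (must be present in `ref`).
#' @param n_components number of components
#'   (<= min(#cells - 1, #HVGs)).
#' @param layer layer to use when `ref` is an experiment.
#' @return a `reference_landscape`: list with `loadings` (HVGs x
#'   components), `centers`, `coords` (cells x components), `labels`,
#'   `hvgs`, `n_components`.
#' @export
fit_reference_pca <- function(ref, labels, hvgs, n_components = 50L,
                              layer = "logcounts") {
  m <- if (methods::is(ref, "SingleCellExperiment"))
    as.matrix(.get_layer(ref, layer)) else as.matrix(ref)
  missing <- setdiff(hvgs, rownames(m))
  if (length(missing))
    stop("HVGs absent from the reference: ",
         paste(head(missing, 5), collapse = ", "))
  if (length(labels) != ncol(m))
    stop("'labels' must have one entry per reference cell")
  if (anyNA(labels)) stop("reference labels must cover all cells")
  X <- t(m[hvgs, , drop = FALSE])            # cells x HVGs
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop(sprintf("n_components = %d exceeds min(#cells - 1, #HVGs) = %d",
                 n_components, min(nrow(X) - 1L, ncol(X))))
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  sv <- svd(Xc, nu = 0, nv = n_components)
  loadings <- sv$v
  rownames(loadings) <- hvgs
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  coords <- Xc %*% loadings
  rownames(coords) <- colnames(m)
  structure(list(loadings = loadings, centers = centers, coords = coords,
                 labels = as.character(labels), hvgs = hvgs,
                 n_components = as.integer(n_components),
                 sdev = sv$d[seq_len(n_components)] / sqrt(max(nrow(X) - 1, 1))),
            class = "reference_landscape")
}

#' Project query cells onto a reference landscape
#'
#' Query expression over the landscape's HVGs is centered with the
#' reference's stored gene means (never the query's own) and multiplied
#' by the reference loadings. HVGs missing from the query are imputed
#' at the reference mean (zero after centering); if fewer than
#' `min_coverage` of the HVGs are present the projection errors, since
#' the geometry is no longer trustworthy.
#'
#' @param query `SingleCellExperiment` or genes x cells matrix.
#' @param landscape a [fit_reference_pca()] result.
#' @param layer layer to use when `query` is an experiment.
#' @param min_coverage minimum fraction of landscape HVGs the query
#'   must contain.
#' @return cells x components coordinate matrix.
#' @export
project_onto_reference <- function(query, landscape, layer = "logcounts",
                                   min_coverage = 0.8) {
  if (!inherits(landscape, "reference_landscape"))
    stop("'landscape' must be a reference_landscape")
  m <- if (methods::is(query, "SingleCellExperiment"))
    as.matrix(.get_layer(query, layer)) else as.matrix(query)
  hvgs <- landscape$hvgs
  present <- intersect(hvgs, rownames(m))
  coverage <- length(present) / length(hvgs)
  if (coverage < min_coverage)
    stop(sprintf("query covers only %.0f%% of landscape HVGs (%d/%d); >= %.0f%% required",
                 100 * coverage, length(present), length(hvgs),
                 100 * min_coverage))
  X <- matrix(0, nrow = ncol(m), ncol = length(hvgs),
              dimnames = list(colnames(m), hvgs))
  X[, present] <- t(m[present, , drop = FALSE])
  # missing genes sit at the reference mean, i.e. zero after centering
  Xc <- sweep(X, 2, landscape$centers)
  Xc[, setdiff(hvgs, present)] <- 0
  Xc %*% landscape$loadings
}

#' k-nearest-neighbor label transfer in PCA space
#'
#' Exact Euclidean k-NN of each query cell against the reference
#' coordinates; the assigned label is the most frequent cell type among
#' the `k` neighbors. Tied modal labels are broken by the smaller
#' summed neighbor distance, then lexicographically, so the assignment
#' is deterministic and independent of reference ordering.
#'
#' @param query_coords cells x components matrix from
#'   [project_onto_reference()].
#' @param landscape a `reference_landscape`.
#' @param k number of neighbors (1 <= k <= #reference cells).
#' @return data.frame: `label`, plus a `votes` attribute (query x label
#'   count matrix).
#' @export
knn_label_transfer <- function(query_coords, landscape, k = 15L) {
  if (!inherits(landscape, "reference_landscape"))
    stop("'landscape' must be a reference_landscape")
  if (k < 1L) stop("'k' must be at least 1")
  ref <- landscape$coords
  if (k > nrow(ref)) stop("'k' exceeds the number of reference cells")
  q <- as.matrix(query_coords)
  labs <- landscape$labels
  lab_levels <- sort(unique(labs))
  # squared Euclidean distances via the expansion ||q||^2 + ||r||^2 - 2 q.r
  d2 <- outer(rowSums(q^2), rowSums(ref^2), "+") - 2 * q %*% t(ref)
  d2[d2 < 0] <- 0
  votes <- matrix(0L, nrow = nrow(q), ncol = length(lab_levels),
                  dimnames = list(rownames(q), lab_levels))
  label <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    nn <- order(d2[i, ], labs)[seq_len(k)]   # stable under distance ties
    tab <- table(labs[nn])
    votes[i, names(tab)] <- as.integer(tab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(l) sum(sqrt(d2[i, nn[labs[nn] == l]])),
                     numeric(1))
      top <- top[order(sums, top)]
    }
    label[i] <- top[1]
  }
  out <- data.frame(label = label, row.names = rownames(q),
                    stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}

#' Two-tier hierarchical cell typing
#'
#' Every query cell is labeled by projection onto the key landscape
#' (the broad HSPC reference); cells whose key label falls in
#' `refine_labels` (by default the stem/immature compartment) are then
#' re-labeled by projection onto the refinement landscape, which
#' resolves the earliest stem and progenitor states at finer grain.
#' Cells outside `refine_labels` keep their key label.
#'
#' @param query `SingleCellExperiment` or genes x cells log-expression
#'   matrix.
#' @param key_landscape,refinement_landscape `reference_landscape`s;
#'   when the refinement landscape is `NULL` the key labels are
#'   returned with a warning.
#' @param refine_labels key labels to refine.
#' @param k neighbors for both transfers.
#' @param layer layer to project when `query` is an experiment.
#' @return data.frame: `key_label`, `label` (final), one row per cell.
#' @export
hierarchical_cell_typing <- function(query, key_landscape,
                                     refinement_landscape = NULL,
                                     refine_labels = c("HSC", "Immature"),
                                     k = 15L, layer = "logcounts") {
  key_coords <- project_onto_reference(query, key_landscape, layer = layer)
  key <- knn_label_transfer(key_coords, key_landscape, k = k)$label
  out <- data.frame(key_label = key, label = key,
                    row.names = rownames(key_coords),
                    stringsAsFactors = FALSE)
  refine <- key %in% refine_labels
  if (!any(refine)) return(out)
  if (is.null(refinement_landscape)) {
    warning("no refinement landscape supplied; returning key labels")
    return(out)
  }
  m <- if (methods::is(query, "SingleCellExperiment"))
    as.matrix(.get_layer(query, layer)) else as.matrix(query)
  sub_coords <- project_onto_reference(m[, refine, drop = FALSE],
                                       refinement_landscape)
  out$label[refine] <- knn_label_transfer(sub_coords, refinement_landscape,
                                          k = k)$label
  out
}

#' Serialize a reference landscape to plain-text files
#'
#' Writes `loadings.csv` (HVGs x components), `centers.csv`,
#' `coords.csv` (reference cells x components) and `labels.tsv`.
#'
#' @param landscape a `reference_landscape`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!inherits(landscape, "reference_landscape"))
    stop("'landscape' must be a reference_landscape")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(landscape$loadings, file.path(dir, "loadings.csv"))
  write.csv(data.frame(gene = names(landscape$centers),
                       center = landscape$centers, row.names = NULL),
            file.path(dir, "centers.csv"), row.names = FALSE)
  write.csv(landscape$coords, file.path(dir, "coords.csv"))
  write.table(data.frame(cell = rownames(landscape$coords),
                         label = landscape$labels),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a serialized reference landscape
#'
#' @param dir directory written by [write_landscape()].
#' @return a `reference_landscape`.
#' @export
read_landscape <- function(dir) {
  f <- function(name) file.path(dir, name)
  for (n in c("loadings.csv", "centers.csv", "coords.csv", "labels.tsv"))
    if (!file.exists(f(n))) stop("missing landscape file: ", f(n))
  loadings <- as.matrix(read.csv(f("loadings.csv"), row.names = 1,
                                 check.names = FALSE))
  centers_df <- read.csv(f("centers.csv"))
  centers <- stats::setNames(centers_df$center, centers_df$gene)
  coords <- as.matrix(read.csv(f("coords.csv"), row.names = 1,
                               check.names = FALSE))
  labels <- read.delim(f("labels.tsv"), stringsAsFactors = FALSE)
  structure(list(loadings = loadings, centers = centers[rownames(loadings)],
                 coords = coords, labels = labels$label,
                 hvgs = rownames(loadings),
                 n_components = ncol(loadings), sdev = NULL),
            class = "reference_landscape")
}
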