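#' Expression matrix container
#'
#' Light-weight container for a cells x features expression matrix together
#' with per-cell metadata. Two layers are distinguished: `"counts"` (raw
#' non-negative integers) and `"lognorm"` (natural-log of size-factor
#' normalised counts plus one).
#'
#' @param values numeric matrix, cells in rows, features in columns.
#' @param layer `"counts"` or `"lognorm"`.
#' @param cell_metadata data.frame with one row per cell. For QC filtering it
#'   must contain `n_genes_over_10rpm`, `log10_total_reads`, `mapped_fraction`,
#'   `mito_fraction` and `spikein_fraction`.
#' @param cluster optional vector of cluster labels, one per cell.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm"),
                              cell_metadata = NULL, cluster = NULL) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix must have at least one cell and one feature")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cell_%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("feature_%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("cell and feature ids must be unique")
  if (layer == "counts") {
    if (any(values < 0)) stop("counts layer must be non-negative")
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts layer must be integer-valued")
  } else {
    if (any(!is.finite(values))) stop("lognorm layer must be finite")
  }
  if (is.null(cell_metadata)) {
    cell_metadata <- data.frame(row.names = rownames(values))
  } else {
    cell_metadata <- as.data.frame(cell_metadata)
    stopifnot(nrow(cell_metadata) == nrow(values))
    rownames(cell_metadata) <- rownames(values)
  }
  if (!is.null(cluster)) {
    stopifnot(length(cluster) == nrow(values))
    cell_metadata$cluster <- cluster
  }
  structure(list(values = values, layer = layer,
                 cell_metadata = cell_metadata),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d features [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (ncol(x$cell_metadata) > 0)
    cat("cell metadata:", paste(colnames(x$cell_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Cell ids of an ExpressionMatrix
#' @param m ExpressionMatrix.
#' @return character vector.
#' @export
cell_ids <- function(m) rownames(m$values)

#' Feature ids of an ExpressionMatrix
#' @param m ExpressionMatrix.
#' @return character vector.
#' @export
feature_ids <- function(m) colnames(m$values)

#' Cluster labels of an ExpressionMatrix
#' @param m ExpressionMatrix.
#' @return vector of labels, or NULL when none assigned.
#' @export
cluster_labels <- function(m) m$cell_metadata$cluster

#' Subset an ExpressionMatrix by cells and/or features
#'
#' @param m ExpressionMatrix.
#' @param cells,features index, logical or id vectors; NULL keeps all.
#' @return ExpressionMatrix.
#' @export
subset_cells <- function(m, cells = NULL, features = NULL) {
  v <- m$values
  meta <- m$cell_metadata
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
  }
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  out <- m
  out$values <- v
  out$cell_metadata <- meta
  out
}

#' Read a counts matrix from MatrixMarket + sidecar TSVs
#'
#' Expects `<prefix>.mtx` (features x cells or cells x features, see
#' `cells_in_rows`), `<prefix>_cells.tsv` (cell ids, optionally metadata
#' columns) and `<prefix>_features.tsv` (feature ids).
#'
#' @param prefix file path prefix.
#' @param cells_in_rows whether the MTX stores cells as rows (default TRUE).
#' @return ExpressionMatrix with a counts layer.
#' @export
read_counts_mtx <- function(prefix, cells_in_rows = TRUE) {
  mm <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  cells <- utils::read.delim(paste0(prefix, "_cells.tsv"),
                             stringsAsFactors = FALSE)
  feats <- utils::read.delim(paste0(prefix, "_features.tsv"),
                             stringsAsFactors = FALSE)
  if (!cells_in_rows) mm <- t(mm)
  rownames(mm) <- cells[[1]]
  colnames(mm) <- feats[[1]]
  meta <- cells[, -1, drop = FALSE]
  rownames(meta) <- cells[[1]]
  expression_matrix(mm, "counts", cell_metadata = meta)
}

#' Write a counts matrix as MatrixMarket + sidecar TSVs
#'
#' @param m ExpressionMatrix (counts layer).
#' @param prefix file path prefix; writes `<prefix>.mtx`,
#'   `<prefix>_cells.tsv`, `<prefix>_features.tsv`.
#' @return invisibly, the prefix.
#' @export
write_counts_mtx <- function(m, prefix) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  cells <- cbind(data.frame(cell_id = cell_ids(m)), m$cell_metadata)
  utils::write.table(cells, paste0(prefix, "_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature_id = feature_ids(m)),
                     paste0(prefix, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
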