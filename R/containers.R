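#' Single-cell expression container
#'
#' A light container for a sparse cell-by-gene count matrix with aligned
#' per-cell and per-gene metadata. Cells are rows, genes are columns; rows of
#' `cell_meta` match matrix rows one-to-one, and rows of `gene_meta` match
#' matrix columns.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, cells x genes,
#'   with cell ids as rownames and gene ids as colnames.
#' @param cell_meta data.frame with one row per cell. Must contain `cell_id`;
#'   typical columns are `individual`, `condition`, `cluster`,
#'   `mito_fraction`, `contamination_score`, `doublet_score`, `true_type`.
#' @param gene_meta data.frame with one row per gene. Must contain `gene_id`;
#'   typical columns are `is_mito` and `marker_of`.
#'
#' @return An object of class `cell_expr`: a list with elements `counts`
#'   (a `dgCMatrix`), `cell_meta`, and `gene_meta`.
#' @examples
#' m <- Matrix::rsparsematrix(5, 10, density = 0.5)
#' m@x <- abs(round(m@x * 10))
#' rownames(m) <- paste0("c", 1:5); colnames(m) <- paste0("g", 1:10)
#' ce <- cell_expr(m, data.frame(cell_id = rownames(m)),
#'                 data.frame(gene_id = colnames(m)))
#' dim(ce)
#' @export
cell_expr <- function(counts, cell_meta, gene_meta) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop_lpc("counts must be nonnegative")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop_lpc("counts must carry cell ids as rownames and gene ids as colnames")
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta)) stop_lpc("cell_meta must have a cell_id column")
  if (!"gene_id" %in% names(gene_meta)) stop_lpc("gene_meta must have a gene_id column")
  if (nrow(cell_meta) != nrow(counts)) stop_lpc("cell_meta rows must match count matrix rows")
  if (nrow(gene_meta) != ncol(counts)) stop_lpc("gene_meta rows must match count matrix columns")
  if (nrow(counts) > 0 &&
      !identical(as.character(cell_meta$cell_id), rownames(counts))) {
    stop_lpc("cell_meta$cell_id must match rownames(counts) in order")
  }
  if (ncol(counts) > 0 &&
      !identical(as.character(gene_meta$gene_id), colnames(counts))) {
    stop_lpc("gene_meta$gene_id must match colnames(counts) in order")
  }
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_expr")
}

#' @export
dim.cell_expr <- function(x) dim(x$counts)

#' @export
print.cell_expr <- function(x, ...) {
  cat(sprintf("<cell_expr> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  cat("gene_meta columns:", paste(names(x$gene_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a cell_expr by cells and/or genes
#'
#' @param x a `cell_expr`.
#' @param i cell index (logical, integer or cell-id character vector).
#' @param j gene index (logical, integer or gene-id character vector).
#' @param ... ignored.
#' @return A `cell_expr` with metadata subset in step with the matrix.
#' @export
`[.cell_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  cell_expr(x$counts[i, j, drop = FALSE],
            x$cell_meta[i, , drop = FALSE],
            x$gene_meta[j, , drop = FALSE])
}

#' Number of detected genes per cell (count > 0)
#' @param x a `cell_expr`.
#' @return Integer vector, one entry per cell.
#' @export
detected_genes <- function(x) {
  stopifnot(inherits(x, "cell_expr"))
  as.integer(Matrix::rowSums(x$counts > 0))
}

#' Total UMI counts per cell
#' @param x a `cell_expr`.
#' @return Numeric vector, one entry per cell.
#' @export
total_counts <- function(x) {
  stopifnot(inherits(x, "cell_expr"))
  as.numeric(Matrix::rowSums(x$counts))
}

#' Mitochondrial count fraction per cell, recomputed from counts
#'
#' Uses the `is_mito` flag in `gene_meta`. Cells with zero total counts get 0.
#' @param x a `cell_expr`.
#' @return Numeric vector in `[0, 1]`.
#' @export
mito_fraction <- function(x) {
  stopifnot(inherits(x, "cell_expr"))
  if (!"is_mito" %in% names(x$gene_meta)) stop_lpc("gene_meta has no is_mito column")
  tot <- total_counts(x)
  mt <- as.numeric(Matrix::rowSums(x$counts[, x$gene_meta$is_mito, drop = FALSE]))
  ifelse(tot > 0, mt / tot, 0)
}

#' Log-normalized expression
#'
#' Per-cell scaling to a fixed library size followed by `log1p`:
#' `log(1 + count / cell_total * scale_factor)`. This is the normalization all
#' downstream z-scores and module scores are computed on.
#'
#' @param x a `cell_expr`.
#' @param scale_factor target per-cell total (default 10000).
#' @return A sparse cells x genes matrix of log-normalized values.
#' @export
lognorm <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "cell_expr"))
  tot <- total_counts(x)
  tot[tot == 0] <- 1
  m <- Matrix::Diagonal(x = scale_factor / tot) %*% x$counts
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(x$counts)
  m
}
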