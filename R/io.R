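#' Write a cell_expr as a Matrix-Market bundle
#'
#' Writes `matrix.mtx` (genes in columns of the in-memory matrix are stored
#' as MTX rows = cells, columns = genes), `genes.tsv` and `cells.tsv`
#' (tab-separated with header) into `dir`.
#'
#' @param expr a [cell_expr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_bundle <- function(expr, dir) {
  stopifnot(inherits(expr, "cell_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(expr$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(expr$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a Matrix-Market expression bundle
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A [cell_expr()].
#' @export
read_expression_bundle <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  rownames(m) <- cells$cell_id
  colnames(m) <- genes$gene_id
  cell_expr(m, cells, genes)
}

#' Write / read a spatial centroid table (cell_id,x,y,cell_type CSV)
#'
#' @param map a `spatial_map` or compatible data.frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `spatial_map` (reader).
#' @export
write_spatial_map <- function(map, path) {
  utils::write.csv(map[, c("cell_id", "x", "y", "cell_type")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spatial_map
#' @export
read_spatial_map <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "cell_type")
  if (!all(need %in% names(out))) {
    stop_lpc("centroid CSV must have columns cell_id, x, y, cell_type")
  }
  class(out) <- c("spatial_map", "data.frame")
  out
}

#' Write a GEM-style spatial expression TSV (geneID, x, y, MIDCount)
#'
#' Emits one row per nonzero (gene, cell) pair, placing the transcripts at
#' the cell's centroid, the per-coordinate transcript table convention of
#' spatial chips.
#'
#' @param expr a [cell_expr()] whose cells match `map$cell_id`.
#' @param map a `spatial_map` giving coordinates for every cell.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_gem_tsv <- function(expr, map, path) {
  stopifnot(inherits(expr, "cell_expr"))
  idx <- match(rownames(expr$counts), map$cell_id)
  if (anyNA(idx)) stop_lpc("every expression cell needs coordinates in the map")
  tm <- methods::as(expr$counts, "TsparseMatrix")
  df <- data.frame(geneID = colnames(expr$counts)[tm@j + 1L],
                   x = map$x[idx][tm@i + 1L],
                   y = map$y[idx][tm@i + 1L],
                   MIDCount = as.integer(tm@x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a linkage as Newick
#'
#' @param tree a linkage from [ward_d_linkage()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_linkage_newick <- function(tree, path) {
  ape::write.tree(as_phylo_linkage(tree), file = path)
  invisible(path)
}
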