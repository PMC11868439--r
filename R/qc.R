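#' Quality-control configuration
#'
#' Cell-level bounds follow the published filtering wording exactly: detected
#' genes strictly above `genes_min` and strictly below `genes_max`; total UMI
#' strictly above `umi_min`; mitochondrial percentage strictly below
#' `mito_max_pct`; ambient-contamination score retained up to and including
#' `contamination_max` ("exceeding" excluded); the top `doublet_rate`
#' fraction of remaining cells by doublet score removed; and genes kept when
#' detected in at least `min_cells_per_gene` retained cells (inclusive).
#'
#' @param genes_min,genes_max exclusive bounds on detected genes per cell
#'   (defaults 200 and 6000).
#' @param umi_min exclusive lower bound on UMI per cell (default 150).
#' @param mito_max_pct exclusive upper bound on mitochondrial percentage
#'   (default 50).
#' @param min_cells_per_gene inclusive gene-level detection floor (default 3).
#' @param contamination_max cells with score strictly above this are removed
#'   (default 0.4).
#' @param doublet_rate fraction of remaining cells removed as putative
#'   doublets (default 0.05; removal count is floor(rate * n)).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(genes_min = 200, genes_max = 6000, umi_min = 150,
                      mito_max_pct = 50, min_cells_per_gene = 3,
                      contamination_max = 0.4, doublet_rate = 0.05) {
  if (genes_min >= genes_max) stop_lpc("genes_min must be below genes_max")
  for (v in c(genes_min, umi_min, mito_max_pct, min_cells_per_gene,
              contamination_max, doublet_rate)) {
    chk_scalar(v, "qc bound", 0)
  }
  structure(list(genes_min = genes_min, genes_max = genes_max,
                 umi_min = umi_min, mito_max_pct = mito_max_pct,
                 min_cells_per_gene = min_cells_per_gene,
                 contamination_max = contamination_max,
                 doublet_rate = doublet_rate),
            class = "qc_config")
}

#' Filter cells on QC metrics and artifact scores
#'
#' Rules are applied in a fixed, documented order — detected-gene bounds,
#' UMI floor, mitochondrial percentage, contamination score, then removal of
#' the top `doublet_rate` fraction of the remaining cells by doublet score
#' (ties broken by cell_id order, count = floor(rate * n)). Each removed
#' cell is attributed to the first rule that rejects it, and the report
#' reconciles exactly.
#'
#' Mitochondrial percentage is taken from the `mito_fraction` metadata
#' column when present, otherwise recomputed from the `is_mito` gene flags.
#' Missing `contamination_score` or `doublet_score` columns cause those
#' rules to be skipped, with an explicit warning recorded in the report.
#'
#' @param expr a [cell_expr()].
#' @param cfg a [qc_config()].
#' @return A list with `expr` (filtered cells, all genes) and `report`
#'   (class `qc_report`).
#' @export
filter_cells <- function(expr, cfg = qc_config()) {
  stopifnot(inherits(expr, "cell_expr"), inherits(cfg, "qc_config"))
  n_in <- nrow(expr$counts)
  genes_det <- detected_genes(expr)
  umi <- total_counts(expr)
  mito_pct <- if ("mito_fraction" %in% names(expr$cell_meta)) {
    expr$cell_meta$mito_fraction * 100
  } else {
    mito_fraction(expr) * 100
  }
  warnings <- character(0)
  removed <- c(gene_bounds = 0L, umi = 0L, mito = 0L,
               contamination = 0L, doublet = 0L)

  alive <- rep(TRUE, n_in)
  fail <- !(genes_det > cfg$genes_min & genes_det < cfg$genes_max)
  removed["gene_bounds"] <- sum(fail & alive); alive <- alive & !fail
  fail <- !(umi > cfg$umi_min)
  removed["umi"] <- sum(fail & alive); alive <- alive & !fail
  fail <- !(mito_pct < cfg$mito_max_pct)
  removed["mito"] <- sum(fail & alive); alive <- alive & !fail

  if ("contamination_score" %in% names(expr$cell_meta)) {
    fail <- expr$cell_meta$contamination_score > cfg$contamination_max
    removed["contamination"] <- sum(fail & alive); alive <- alive & !fail
  } else {
    warnings <- c(warnings, "contamination_score column missing; contamination rule skipped")
    warning(warnings[length(warnings)])
  }
  if ("doublet_score" %in% names(expr$cell_meta)) {
    n_rem <- sum(alive)
    n_drop <- floor(cfg$doublet_rate * n_rem)
    if (n_drop > 0) {
      idx <- which(alive)
      # ties broken by cell_id order: stable sort on descending score
      ord <- idx[order(-expr$cell_meta$doublet_score[idx],
                       expr$cell_meta$cell_id[idx])]
      drop <- ord[seq_len(n_drop)]
      alive[drop] <- FALSE
      removed["doublet"] <- n_drop
    }
  } else {
    warnings <- c(warnings, "doublet_score column missing; doublet rule skipped")
    warning(warnings[length(warnings)])
  }

  out <- expr[alive, ]
  report <- structure(list(
    n_cells_in = n_in, n_cells_out = sum(alive),
    n_genes_in = ncol(expr$counts), n_genes_out = ncol(expr$counts),
    removed_by_rule = as.list(removed),
    rule_order = c("gene_bounds", "umi", "mito", "contamination", "doublet"),
    warnings = warnings), class = "qc_report")
  stopifnot(report$n_cells_out + sum(removed) == n_in)
  list(expr = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> cells %d -> %d; genes %d -> %d\n",
              x$n_cells_in, x$n_cells_out, x$n_genes_in, x$n_genes_out))
  for (r in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-13s %d\n", paste0(r, ":"), x$removed_by_rule[[r]]))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Filter genes by detection across retained cells
#'
#' A gene is retained when it has a nonzero count in at least
#' `min_cells_per_gene` cells (inclusive). Intended to run after
#' [filter_cells()].
#'
#' @param expr a [cell_expr()] (cell-filtered).
#' @param cfg a [qc_config()].
#' @return A filtered [cell_expr()].
#' @export
filter_genes <- function(expr, cfg = qc_config()) {
  stopifnot(inherits(expr, "cell_expr"), inherits(cfg, "qc_config"))
  if (nrow(expr$counts) == 0) stop_lpc("no cells left to filter genes on")
  keep <- Matrix::colSums(expr$counts > 0) >= cfg$min_cells_per_gene
  if (!any(keep)) stop_lpc("no genes pass the detection filter")
  expr[, which(keep)]
}

#' Run the full QC stage (cells then genes)
#'
#' @param expr a [cell_expr()].
#' @param cfg a [qc_config()].
#' @return A list with `expr` and `report`; the report's gene counts reflect
#'   the gene filter.
#' @export
qc_filter <- function(expr, cfg = qc_config()) {
  step1 <- filter_cells(expr, cfg)
  out <- filter_genes(step1$expr, cfg)
  step1$report$n_genes_out <- ncol(out$counts)
  list(expr = out, report = step1$report)
}
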