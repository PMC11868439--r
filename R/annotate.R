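#' Default marker panels for liver cell-type annotation
#'
#' Hepatocyte (PCK1, TF, ALB, HP), cholangiocyte (SOX9, KRT7, KRT18, SOX4)
#' and progenitor (EPCAM, PCNA, HNF1A, CDK1, CD24, TACSTD2, NFKB1) panels
#' drive the bipotency rule identifying the LPC cluster; LPC1-LPC3 subtype
#' panels support re-annotation of LPC subpopulations (functional
#' restoration, activation, and cell transition states respectively).
#'
#' @return Named list of gene vectors of class `marker_panels`.
#' @export
default_marker_panels <- function() {
  p <- list(
    hepatocyte    = c("PCK1", "TF", "ALB", "HP"),
    cholangiocyte = c("SOX9", "KRT7", "KRT18", "SOX4"),
    progenitor    = c("EPCAM", "PCNA", "HNF1A", "CDK1", "CD24", "TACSTD2",
                      "NFKB1"),
    endothelial   = c("PECAM1", "VWF", "CDH5"),
    HSC           = c("ACTA2", "COL1A1", "DCN"),
    macrophage    = c("CD68", "LYZ", "CD163"),
    T_cell        = c("CD3D", "CD3E", "CD2"),
    B_cell        = c("CD79A", "MS4A1"),
    LPC1          = c("ALB", "APOA1"),
    LPC2          = c("STMN1", "NPM1", "ACTB", "PTMA"),
    LPC3          = c("S100A6", "S100A4")
  )
  structure(p, class = c("marker_panels", "list"))
}

#' The 14-gene liver-regeneration signature
#'
#' Gene set scored per cell with [score_gene_module()] to contrast
#' regeneration programs across conditions and cell types.
#' @return Character vector of 14 gene symbols.
#' @export
regeneration_gene_set <- function() {
  c("EPCAM", "TACSTD2", "FGFR2", "TM4SF4", "CLDN1", "ANXA4", "WWTR1",
    "MYC", "STMN1", "PSMA4", "SNRPB", "ERH", "NME1", "TMEM14B")
}

#' Gene-by-cluster z-scores of mean log-normalized expression
#'
#' For each gene, the per-cluster mean of log-normalized expression is
#' standardized across clusters: z = (m - mean(m)) / sd(m) with the sample
#' sd (ddof 1). A positive z means the gene is expressed above its overall
#' cluster-average level in that cluster. Genes whose cluster means do not
#' vary get an all-zero row.
#'
#' @param expr a [cell_expr()].
#' @param clusters per-cell cluster labels (defaults to the metadata
#'   `cluster` column); at least 2 distinct clusters required.
#' @return A list of class `zscore_matrix`: `z` (genes x clusters) and
#'   `means` (the underlying cluster means).
#' @export
cluster_mean_zscores <- function(expr, clusters = expr$cell_meta$cluster) {
  stopifnot(inherits(expr, "cell_expr"))
  cl <- as.character(clusters)
  if (length(unique(cl)) < 2) stop_lpc("need at least 2 clusters")
  ln <- lognorm(expr)
  levs <- sort(unique(cl))
  means <- sapply(levs, function(l) Matrix::colMeans(ln[cl == l, , drop = FALSE]))
  mu <- rowMeans(means)
  sd <- apply(means, 1, stats::sd)
  z <- (means - mu) / sd
  z[sd == 0, ] <- 0
  structure(list(z = z, means = means), class = "zscore_matrix")
}

panel_mean_z <- function(z, panel) {
  genes <- intersect(panel, rownames(z))
  if (length(genes) == 0) return(NULL)
  if (length(genes) < length(panel)) {
    warning(sprintf("%d panel gene(s) missing from the z matrix",
                    length(panel) - length(genes)))
  }
  colMeans(z[genes, , drop = FALSE])
}

#' Assign a cell type to every cluster from marker-panel z-scores
#'
#' Each cluster receives the label of the panel with the highest mean
#' z-score, provided that maximum reaches `min_z`; otherwise it is
#' "unassigned". Ties are broken deterministically by panel name order.
#' Panel genes missing from the matrix are dropped with a warning; a panel
#' with no genes present is an error.
#'
#' @param z a `zscore_matrix` from [cluster_mean_zscores()].
#' @param panels named list of marker panels (subset used for assignment;
#'   the LPC subtype panels and `progenitor` are excluded from the argmax by
#'   default via `exclude`).
#' @param min_z assignment threshold on the panel-mean z (default 0).
#' @param exclude panel names not competing in the argmax.
#' @return A list of class `cell_type_assignment`: `assignment` (named
#'   character, cluster -> type), `panel_z` (panel x cluster matrix).
#' @export
assign_cell_types <- function(z, panels = default_marker_panels(), min_z = 0,
                              exclude = c("progenitor", "LPC1", "LPC2", "LPC3")) {
  stopifnot(inherits(z, "zscore_matrix"))
  use <- setdiff(names(panels), exclude)
  pz <- list()
  for (p in use) {
    v <- panel_mean_z(z$z, panels[[p]])
    if (is.null(v)) stop_lpc(sprintf("no genes of panel '%s' present", p))
    pz[[p]] <- v
  }
  pz <- do.call(rbind, pz)
  lab <- apply(pz, 2, function(col) {
    best <- which(col == max(col))[1]  # panel name order breaks ties
    if (col[best] >= min_z) rownames(pz)[best] else "unassigned"
  })
  structure(list(assignment = lab, panel_z = pz),
            class = "cell_type_assignment")
}

#' @export
print.cell_type_assignment <- function(x, ...) {
  cat("<cell_type_assignment>\n")
  print(x$assignment)
  invisible(x)
}

#' Flag bipotent LPC clusters
#'
#' A cluster is flagged as an LPC cluster when it simultaneously shows
#' elevated progenitor, hepatocyte AND cholangiocyte panel signal: all three
#' panel-mean z-scores must reach `tau`. This encodes the bipotency
#' signature (progenitor markers plus co-expression of both epithelial
#' lineage panels) that distinguishes liver progenitors from pure lineages.
#' Flags are monotone non-increasing in `tau`.
#'
#' @param z a `zscore_matrix`.
#' @param panels marker panels containing `progenitor`, `hepatocyte`,
#'   `cholangiocyte`.
#' @param tau threshold on each panel-mean z (default 0.5).
#' @return Named logical vector over clusters.
#' @export
identify_lpc_clusters <- function(z, panels = default_marker_panels(),
                                  tau = 0.5) {
  stopifnot(inherits(z, "zscore_matrix"))
  need <- c("progenitor", "hepatocyte", "cholangiocyte")
  if (!all(need %in% names(panels))) {
    stop_lpc("panels must include progenitor, hepatocyte and cholangiocyte")
  }
  pz <- sapply(need, function(p) {
    v <- panel_mean_z(z$z, panels[[p]])
    if (is.null(v)) stop_lpc(sprintf("no genes of panel '%s' present", p))
    v
  })
  flags <- apply(pz >= tau, 1, all)
  names(flags) <- colnames(z$z)
  flags
}

#' Binned-control gene-set module score
#'
#' Per-cell score of a gene set against expression-matched controls: all
#' genes are ranked by mean log-normalized expression and cut into `n_bins`
#' equal-frequency bins; for each set gene, `n_ctrl` control genes are drawn
#' with replacement from its bin; the score is the mean expression of the
#' set genes minus the mean expression of the pooled controls. Cells with a
#' flat expression profile therefore score exactly 0, and a random gene set
#' scores 0 in expectation.
#'
#' @param expr a [cell_expr()].
#' @param gene_set character vector; genes absent from the matrix are
#'   dropped (error if none remain).
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl controls per set gene (default 100), sampled with
#'   replacement.
#' @param seed integer seed for the control draw.
#' @return Numeric vector, one score per cell.
#' @export
score_gene_module <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                              seed = 1L) {
  stopifnot(inherits(expr, "cell_expr"))
  ln <- lognorm(expr)
  genes <- colnames(ln)
  set <- intersect(gene_set, genes)
  if (length(set) == 0) stop_lpc("gene set entirely absent from the matrix")
  avg <- Matrix::colMeans(ln)
  n_bins <- min(n_bins, length(genes))
  # equal-frequency bins of the average-expression ranking
  bin <- ceiling(rank(avg, ties.method = "first") / (length(genes) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  local_seed(seed, {
    # score = mean over (set gene, control) pairs of the expression
    # difference; identical to set mean minus pooled-control mean (every set
    # gene draws n_ctrl controls) but exactly zero on flat cells
    acc <- numeric(nrow(ln))
    for (g in set) {
      pool <- genes[bin == bin[match(g, genes)]]
      ctrl <- sample(pool, n_ctrl, replace = TRUE)
      d <- as.numeric(ln[, g]) - as.matrix(ln[, ctrl, drop = FALSE])
      acc <- acc + Matrix::rowSums(d)
    }
    as.numeric(acc / (length(set) * n_ctrl))
  })
}

#' Per-individual LPC proportions within the epithelial + LPC compartment
#'
#' The denominator is restricted to cells labeled hepatocyte, cholangiocyte
#' or LPC; the proportion is LPC cells over that total, per individual.
#' Individuals with no epithelial or LPC cells are excluded from the cohort
#' statistics with a message. Optionally compares proportion vectors between
#' groups with the shared rank-sum engine.
#'
#' @param cell_types per-cell type labels (must use "hepatocyte",
#'   "cholangiocyte" and "LPC" for the compartment; other labels are
#'   ignored in the denominator).
#' @param individuals per-cell individual ids.
#' @param lpc_label label counting as LPC (default "LPC").
#' @param epithelial_labels labels forming the epithelial denominator.
#' @param groups optional named list of individual-id vectors; all pairwise
#'   two-sided rank-sum tests between their proportion vectors are run.
#' @return A list of class `lpc_proportions`: `per_individual` (data.frame
#'   individual, n_epi_lpc, n_lpc, proportion), `mean`, `sd`, `n`, and
#'   optionally `tests`.
#' @export
lpc_proportions <- function(cell_types, individuals, lpc_label = "LPC",
                            epithelial_labels = c("hepatocyte", "cholangiocyte"),
                            groups = NULL) {
  if (length(cell_types) != length(individuals)) {
    stop_lpc("cell_types and individuals must have equal length")
  }
  keep <- cell_types %in% c(lpc_label, epithelial_labels)
  inds <- sort(unique(individuals))
  denom <- tapply(keep, individuals, sum)[inds]
  nlpc <- tapply(cell_types == lpc_label & keep, individuals, sum)[inds]
  denom[is.na(denom)] <- 0; nlpc[is.na(nlpc)] <- 0
  empty <- denom == 0
  if (any(empty)) {
    message("excluding individuals with no epithelial or LPC cells: ",
            paste(inds[empty], collapse = ", "))
  }
  per <- data.frame(individual = inds[!empty],
                    n_epi_lpc = as.integer(denom[!empty]),
                    n_lpc = as.integer(nlpc[!empty]),
                    proportion = as.numeric(nlpc[!empty] / denom[!empty]),
                    stringsAsFactors = FALSE)
  tests <- NULL
  if (!is.null(groups)) {
    gn <- names(groups)
    tests <- list()
    for (a in seq_along(gn)) {
      for (b in seq_along(gn)) {
        if (b <= a) next
        pa <- per$proportion[per$individual %in% groups[[a]]]
        pb <- per$proportion[per$individual %in% groups[[b]]]
        if (length(pa) && length(pb)) {
          t <- rank_sum_test(pa, pb)
          tests[[paste(gn[a], gn[b], sep = "_vs_")]] <- t$p.value
        }
      }
    }
  }
  structure(list(per_individual = per,
                 mean = mean(per$proportion),
                 sd = stats::sd(per$proportion),
                 n = nrow(per), tests = tests),
            class = "lpc_proportions")
}

#' @export
print.lpc_proportions <- function(x, ...) {
  cat(sprintf("<lpc_proportions> %.2f%% +/- %.2f%% (n=%d)\n",
              100 * x$mean, 100 * x$sd, x$n))
  invisible(x)
}

#' Annotate a cohort end to end
#'
#' Convenience wrapper running [cluster_mean_zscores()],
#' [assign_cell_types()] and [identify_lpc_clusters()], then projecting the
#' cluster-level labels onto cells. Clusters flagged as LPC are labeled
#' "LPC" regardless of their argmax panel.
#'
#' @param expr a QC-filtered [cell_expr()] with a `cluster` metadata column.
#' @param panels marker panels.
#' @param tau bipotency threshold passed to [identify_lpc_clusters()].
#' @param min_z assignment threshold passed to [assign_cell_types()].
#' @return A list: `cell_type` (per-cell labels), `cluster_type` (cluster ->
#'   label), `lpc_flags`, `zscores`, `assignment`.
#' @export
annotate_cohort <- function(expr, panels = default_marker_panels(),
                            tau = 0.5, min_z = 0) {
  z <- cluster_mean_zscores(expr)
  asg <- assign_cell_types(z, panels, min_z = min_z)
  flags <- identify_lpc_clusters(z, panels, tau = tau)
  cluster_type <- asg$assignment
  cluster_type[names(flags)[flags]] <- "LPC"
  cell_type <- cluster_type[as.character(expr$cell_meta$cluster)]
  list(cell_type = unname(cell_type), cluster_type = cluster_type,
       lpc_flags = flags, zscores = z, assignment = asg)
}
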