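#' Per-source-cell mean distance to the k nearest cells of each type
#'
#' For every cell of `source_type` and every target cell type, computes the
#' mean Euclidean centroid distance to the k nearest cells of that type. The
#' source cell is excluded from its own type's neighbour pool. A target type
#' with fewer than k cells (after self-exclusion) yields `NA` — recorded as
#' missing, never silently zero.
#'
#' @param map a `spatial_map` (or any data.frame with `cell_id`, `x`, `y`,
#'   `cell_type`).
#' @param source_type type of the source cells (default "LPC").
#' @param k neighbours per type (default 4).
#' @return A list of class `distance_profiles`: `profiles` (source cells x
#'   types matrix of mean distances), `k`, `source_type`, and `raw` (list of
#'   source x k distance matrices per type, for audit).
#' @examples
#' m <- simulate_spatial(spatial_sim_config(seed = 1))
#' p <- knn_type_distance_profiles(m, "LPC", k = 4)
#' head(p$profiles)
#' @export
knn_type_distance_profiles <- function(map, source_type = "LPC", k = 4) {
  if (k < 1) stop_lpc("k must be >= 1")
  if (nrow(map) == 0) stop_lpc("map is empty")
  if (!source_type %in% map$cell_type) {
    stop_lpc(sprintf("source type '%s' absent from the map", source_type))
  }
  src <- map[map$cell_type == source_type, , drop = FALSE]
  types <- sort(unique(map$cell_type))
  prof <- matrix(NA_real_, nrow(src), length(types),
                 dimnames = list(src$cell_id, types))
  raw <- list()
  for (t in types) {
    tgt <- map[map$cell_type == t, , drop = FALSE]
    rawm <- matrix(NA_real_, nrow(src), k, dimnames = list(src$cell_id, NULL))
    for (i in seq_len(nrow(src))) {
      dx <- tgt$x - src$x[i]
      dy <- tgt$y - src$y[i]
      dd <- sqrt(dx^2 + dy^2)
      if (t == source_type) dd <- dd[tgt$cell_id != src$cell_id[i]]
      if (length(dd) >= k) {
        kd <- sort(dd, partial = k)[seq_len(k)]
        rawm[i, ] <- sort(kd)
        prof[i, t] <- mean(kd)
      }
    }
    raw[[t]] <- rawm
  }
  structure(list(profiles = prof, k = k, source_type = source_type, raw = raw),
            class = "distance_profiles")
}

#' @export
print.distance_profiles <- function(x, ...) {
  cat(sprintf("<distance_profiles> %d %s cells x %d types (k=%d)\n",
              nrow(x$profiles), x$source_type, ncol(x$profiles), x$k))
  invisible(x)
}

#' Rank target types by spatial proximity to the source cells
#'
#' Types are ordered by ascending median of the per-source-cell mean kNN
#' distance; the nearest-ranked types are the source population's spatial
#' neighbours. Columns that are entirely missing are excluded with a
#' message.
#'
#' @param profiles a `distance_profiles` object.
#' @return data.frame ordered by `median`: columns `cell_type`, `median`,
#'   `q25`, `q75`, `n`.
#' @export
rank_colocalization <- function(profiles) {
  stopifnot(inherits(profiles, "distance_profiles"))
  p <- profiles$profiles
  keep <- colSums(!is.na(p)) > 0
  if (!any(keep)) stop_lpc("no valid columns to rank")
  if (any(!keep)) {
    message("excluding all-missing type columns: ",
            paste(colnames(p)[!keep], collapse = ", "))
  }
  p <- p[, keep, drop = FALSE]
  out <- data.frame(
    cell_type = colnames(p),
    median = apply(p, 2, stats::median, na.rm = TRUE),
    q25 = apply(p, 2, stats::quantile, probs = 0.25, na.rm = TRUE),
    q75 = apply(p, 2, stats::quantile, probs = 0.75, na.rm = TRUE),
    n = colSums(!is.na(p)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$median), , drop = FALSE]
}

#' Cluster source cells by their distance profiles
#'
#' Groups source cells with similar spatial microenvironments: missing
#' entries are imputed by the column median, profiles are log1p-transformed
#' and per-column standardized, and the rows are clustered with the same
#' Ward (ward.D) engine used for cellular modules, on Euclidean row
#' distances, cut at `k_groups`.
#'
#' @param profiles a `distance_profiles` object.
#' @param k_groups number of groups.
#' @return A list: `groups` (named integer vector per source cell), `tree`
#'   (the linkage).
#' @export
cluster_distance_profiles <- function(profiles, k_groups = 2) {
  stopifnot(inherits(profiles, "distance_profiles"))
  p <- profiles$profiles
  if (nrow(p) < k_groups) stop_lpc("fewer source cells than k_groups")
  for (j in seq_len(ncol(p))) {
    med <- stats::median(p[, j], na.rm = TRUE)
    p[is.na(p[, j]), j] <- med
  }
  p <- p[, !is.na(colSums(p)), drop = FALSE]
  x <- log1p(p)
  sds <- apply(x, 2, stats::sd)
  x <- sweep(x, 2, colMeans(x), "-")
  x[, sds > 0] <- sweep(x[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  tree <- ward_d_linkage(stats::dist(x))
  groups <- cut_modules(tree, k_groups)
  names(groups) <- rownames(p)
  list(groups = groups, tree = tree)
}

#' Pseudo-bulk expression profile of a cell subset
#'
#' Gene-wise count sums over the subset, scaled to counts per million, then
#' log1p. Scale-invariant: doubling every cell's counts leaves the profile
#' unchanged.
#'
#' @param expr a [cell_expr()].
#' @param cells cell index (logical, integer or cell-id character); default
#'   all cells.
#' @param label population label carried on the result.
#' @return A list of class `pseudobulk_profile`: `log_cpm` (named numeric
#'   per gene), `n_cells`, `label`.
#' @export
pseudobulk_profile <- function(expr, cells = NULL, label = "pseudobulk") {
  stopifnot(inherits(expr, "cell_expr"))
  sub <- if (is.null(cells)) expr else expr[cells, ]
  if (nrow(sub$counts) == 0) stop_lpc("empty cell subset")
  s <- Matrix::colSums(sub$counts)
  tot <- sum(s)
  if (tot == 0) stop_lpc("subset has zero total counts")
  structure(list(log_cpm = log1p(s / tot * 1e6),
                 n_cells = nrow(sub$counts), label = label),
            class = "pseudobulk_profile")
}

#' Pearson concordance of two pseudo-bulk profiles
#'
#' Correlates the two log-CPM vectors over their shared gene universe.
#'
#' @param a,b `pseudobulk_profile` objects.
#' @return Pearson r (scalar).
#' @export
pseudobulk_correlation <- function(a, b) {
  stopifnot(inherits(a, "pseudobulk_profile"), inherits(b, "pseudobulk_profile"))
  shared <- intersect(names(a$log_cpm), names(b$log_cpm))
  if (length(shared) < 3) stop_lpc("need at least 3 shared genes")
  va <- a$log_cpm[shared]; vb <- b$log_cpm[shared]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_lpc("zero-variance profile on the shared gene universe")
  }
  as.numeric(stats::cor(va, vb))
}
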