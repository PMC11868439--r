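#' Cluster-by-sample frequency table
#'
#' @param values matrix of proportions, clusters x sample units; every
#'   column must sum to 1 within 1e-9.
#' @param sample_meta data.frame with one row per column: `unit`, and
#'   optionally `individual` and `condition`.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop_lpc("frequencies must lie in [0, 1]")
  }
  cs <- colSums(values)
  if (any(abs(cs - 1) > 1e-9)) stop_lpc("every column must sum to 1")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (nrow(sample_meta) != ncol(values)) {
    stop_lpc("sample_meta must have one row per column of values")
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d clusters x %d sample units\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Cluster frequencies per sample unit
#'
#' Tabulates per-cell cluster labels into a cluster-by-unit proportion
#' matrix, the input to cellular-module discovery. Units with zero cells are
#' dropped with a message.
#'
#' @param clusters per-cell cluster labels.
#' @param units per-cell sample-unit labels (individual by default; pass the
#'   condition column to aggregate by condition instead).
#' @param meta optional data.frame with one row per unit (columns `unit`,
#'   `individual`, `condition`) carried into the result.
#' @return A [freq_table()].
#' @examples
#' cluster_frequency_table(c("A", "A", "B", "B", "B"), rep("u1", 5))
#' @export
cluster_frequency_table <- function(clusters, units, meta = NULL) {
  if (length(clusters) != length(units)) {
    stop_lpc("clusters and units must have equal length")
  }
  tab <- table(cluster = as.character(clusters), unit = as.character(units))
  tot <- colSums(tab)
  empty <- tot == 0
  if (any(empty)) {
    message("dropping empty sample units: ",
            paste(colnames(tab)[empty], collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
    tot <- tot[!empty]
  }
  vals <- sweep(unclass(tab), 2, tot, "/")
  if (is.null(meta)) {
    meta <- data.frame(unit = colnames(vals), stringsAsFactors = FALSE)
  } else {
    meta <- meta[match(colnames(vals), meta$unit), , drop = FALSE]
  }
  freq_table(vals, meta)
}

#' Pairwise Pearson correlation of cluster frequencies and its distance
#'
#' Correlates cluster frequency rows across sample units and converts to the
#' correlation distance d = 1 - r in [0, 2]. A cluster whose frequency does
#' not vary across units has undefined correlations; these are set to 0
#' (distance 1) with a message.
#'
#' @param freq a [freq_table()] with at least 3 sample units.
#' @return A list with `r` (correlation matrix, unit diagonal) and `d`
#'   (distance matrix, zero diagonal).
#' @export
frequency_correlation <- function(freq) {
  stopifnot(inherits(freq, "freq_table"))
  if (ncol(freq$values) < 3) stop_lpc("need at least 3 sample units")
  v <- freq$values
  sds <- apply(v, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(v), method = "pearson"))
  if (any(sds == 0)) {
    message("zero-variance cluster rows, correlations set to 0: ",
            paste(rownames(v)[sds == 0], collapse = ", "))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  d <- 1 - r
  diag(d) <- 0
  list(r = r, d = d)
}

#' Agglomerative Ward linkage on supplied dissimilarities (ward.D dialect)
#'
#' Applies the Lance-Williams recurrence with Ward coefficients DIRECTLY to
#' the supplied dissimilarities, without squaring them first:
#' \deqn{d(k, i \cup j) = \frac{(n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) -
#'   n_k d(i,j)}{n_i + n_j + n_k}}
#' with the nearest active pair merged at each step. This is the "ward.D"
#' dialect; the squared-input variant (`dialect = "ward.D2"`) squares the
#' input, runs the same recurrence, and reports square-root merge heights.
#' Ties are broken by the lexicographically lowest pair of minimum leaf
#' indices.
#'
#' @param d a `dist` object or a square symmetric nonnegative matrix with a
#'   zero diagonal.
#' @param dialect `"ward.D"` (default, unsquared) or `"ward.D2"`.
#' @return An object of class `c("lpc_linkage", "hclust")` with the standard
#'   `merge`, `height`, `order` and `labels` components, usable with
#'   [stats::cutree()] and [as_phylo_linkage()].
#' @examples
#' d <- matrix(c(0, .1, 1, 1,  .1, 0, 1, 1,  1, 1, 0, .1,  1, 1, .1, 0), 4)
#' ward_d_linkage(d)$height
#' @export
ward_d_linkage <- function(d, dialect = c("ward.D", "ward.D2")) {
  dialect <- match.arg(dialect)
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop_lpc("need at least 2 leaves")
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop_lpc("d must be square, symmetric with zero diagonal")
  }
  if (any(d < 0)) stop_lpc("dissimilarities must be nonnegative")
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (dialect == "ward.D2") d <- d^2

  dm <- d
  size <- rep(1L, n)           # cluster sizes, indexed by active slot
  id <- -seq_len(n)            # hclust id: negative leaf, positive merge row
  minleaf <- seq_len(n)        # lowest original leaf index per slot
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    # scan pairs in lexicographic minleaf order; strict < keeps the first
    ord <- act[order(minleaf[act])]
    best <- Inf; bi <- 0L; bj <- 0L
    for (a in seq_len(length(ord) - 1L)) {
      i <- ord[a]
      for (b in seq((a + 1L), length(ord))) {
        j <- ord[b]
        if (dm[i, j] < best) {
          best <- dm[i, j]; bi <- i; bj <- j
        }
      }
    }
    i <- bi; j <- bj
    # hclust merge-row convention: two leaves ascending by leaf index
    # (-1 before -2), a leaf before a cluster, two clusters ascending
    a <- id[i]; b <- id[j]
    merge[s, ] <- if (a < 0 && b < 0) {
      c(max(a, b), min(a, b))
    } else if (a < 0 || b < 0) {
      c(min(a, b), max(a, b))
    } else {
      c(min(a, b), max(a, b))
    }
    height[s] <- best
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      newd <- ((ni + nk) * dm[k, i] + (nj + nk) * dm[k, j] - nk * best) /
        (ni + nj + nk)
      dm[k, i] <- newd; dm[i, k] <- newd
    }
    size[i] <- ni + nj
    id[i] <- s
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active[j] <- FALSE
  }
  if (dialect == "ward.D2") height <- sqrt(height)

  out <- list(merge = merge, height = height,
              order = linkage_leaf_order(merge, n),
              labels = labels, method = dialect,
              dist.method = "user-supplied", call = match.call())
  class(out) <- c("lpc_linkage", "hclust")
  out
}

# leaf order for plotting: in-order traversal of the merge tree
linkage_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  as.integer(walk(n - 1L))
}

#' Convert a linkage to an ape phylogeny (for Newick export)
#'
#' @param tree an object from [ward_d_linkage()].
#' @return An `ape::phylo` with merge heights as branch lengths.
#' @export
as_phylo_linkage <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::as.phylo(tree)
}

#' Cut a linkage into k modules
#'
#' Undoes the last k - 1 merges of the agglomeration, yielding the k-group
#' partition. Module ids are 1..k in order of first appearance of each group
#' among the leaves.
#'
#' @param tree a linkage from [ward_d_linkage()] (or any `hclust`).
#' @param k number of modules, 1 <= k <= number of leaves.
#' @return Named integer vector mapping each leaf label to its module id.
#' @export
cut_modules <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$height) + 1L
  if (k < 1 || k > n) stop_lpc("k must be between 1 and the number of leaves")
  stats::cutree(tree, k = k)
}

#' Rank-sum marker genes per cellular module
#'
#' For each module, cells belonging to its clusters are contrasted against
#' all remaining cells with a two-sided Wilcoxon rank-sum test per gene on
#' log-normalized expression (exact enumeration when both groups are small,
#' tie-corrected normal approximation otherwise), BH adjustment across genes
#' within the contrast, and genes with adjusted p below `alpha` ranked by
#' log2 fold-change of mean normalized expression (pseudocount 1).
#'
#' @param expr a [cell_expr()].
#' @param modules named integer vector mapping cluster label to module id
#'   (as from [cut_modules()]).
#' @param clusters per-cell cluster labels (defaults to
#'   `expr$cell_meta$cluster`).
#' @param top_n genes retained per module after filtering/ranking
#'   (default 250).
#' @param alpha adjusted-p cutoff for the top set (default 0.01).
#' @param min_cells modules with fewer cells are skipped with a message.
#' @return A list with `table` (per-module, per-gene data.frame: log2fc,
#'   statistic, p, p_adj, frac_in, frac_out) and `top` (named list of
#'   top-`top_n` gene vectors per module).
#' @export
module_markers <- function(expr, modules, clusters = expr$cell_meta$cluster,
                           top_n = 250, alpha = 0.01, min_cells = 3) {
  stopifnot(inherits(expr, "cell_expr"))
  cl <- as.character(clusters)
  mod <- modules[cl]
  if (anyNA(mod)) stop_lpc("some cells belong to clusters absent from the module map")
  ln <- as.matrix(lognorm(expr))  # dense: column access dominates below
  norm <- expm1(ln)  # normalized (counts per 1e4) scale for fold-changes
  res <- list()
  tops <- list()
  for (m in sort(unique(modules))) {
    in_m <- mod == m
    if (sum(in_m) < min_cells) {
      message(sprintf("module %s has fewer than %d cells; contrast skipped",
                      m, min_cells))
      next
    }
    mu_in <- Matrix::colMeans(norm[in_m, , drop = FALSE])
    mu_out <- Matrix::colMeans(norm[!in_m, , drop = FALSE])
    l2fc <- log2((mu_in + 1) / (mu_out + 1))
    stat <- p <- numeric(ncol(ln))
    for (g in seq_len(ncol(ln))) {
      t <- rank_sum_test(ln[in_m, g], ln[!in_m, g])
      stat[g] <- t$statistic; p[g] <- t$p.value
    }
    padj <- stats::p.adjust(p, method = "BH")
    frac_in <- Matrix::colMeans(expr$counts[in_m, , drop = FALSE] > 0)
    frac_out <- Matrix::colMeans(expr$counts[!in_m, , drop = FALSE] > 0)
    tab <- data.frame(gene = colnames(ln), module = m, log2fc = l2fc,
                      statistic = stat, p = p, p_adj = padj,
                      frac_in = frac_in, frac_out = frac_out,
                      row.names = NULL, stringsAsFactors = FALSE)
    sig <- tab[tab$p_adj < alpha & tab$log2fc > 0, , drop = FALSE]
    sig <- sig[order(sig$log2fc, decreasing = TRUE), , drop = FALSE]
    tops[[as.character(m)]] <- utils::head(sig$gene, top_n)
    res[[as.character(m)]] <- tab
  }
  list(table = do.call(rbind, res), top = tops)
}

#' Fraction of cells expressing a gene set, per module
#'
#' For each module and each gene set, reports the fraction of cells with
#' nonzero counts, averaged over the set, within the module and in its
#' complement.
#'
#' @param expr a [cell_expr()].
#' @param gene_sets named list of gene vectors.
#' @param modules named integer vector cluster -> module id.
#' @param clusters per-cell cluster labels.
#' @return data.frame with columns `set`, `module`, `frac_in`, `frac_out`.
#' @export
fraction_expressing <- function(expr, gene_sets, modules,
                                clusters = expr$cell_meta$cluster) {
  stopifnot(inherits(expr, "cell_expr"))
  if (any(lengths(gene_sets) == 0)) stop_lpc("gene sets must be nonempty")
  mod <- modules[as.character(clusters)]
  out <- list()
  for (s in names(gene_sets)) {
    genes <- intersect(gene_sets[[s]], colnames(expr$counts))
    det <- expr$counts[, genes, drop = FALSE] > 0
    for (m in sort(unique(modules))) {
      in_m <- mod == m
      fi <- if (length(genes)) mean(Matrix::rowMeans(det[in_m, , drop = FALSE])) else 0
      fo <- if (length(genes)) mean(Matrix::rowMeans(det[!in_m, , drop = FALSE])) else 0
      out[[length(out) + 1L]] <- data.frame(set = s, module = m,
                                            frac_in = fi, frac_out = fo,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
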