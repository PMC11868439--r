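# Shared fixtures and independent oracles used across the suite.

# Build a small cell_expr from a dense matrix (ids synthesized).
make_expr <- function(m, cluster = NULL, individual = NULL, extra = list()) {
  rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  cm <- data.frame(cell_id = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(cluster)) cm$cluster <- cluster
  if (!is.null(individual)) cm$individual <- individual
  for (nm in names(extra)) cm[[nm]] <- extra[[nm]]
  gm <- data.frame(gene_id = colnames(m), is_mito = FALSE,
                   stringsAsFactors = FALSE)
  cell_expr(m, cm, gm)
}

# Adjusted Rand Index, written from the contingency-table definition.
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  sij <- sum(choose(t, 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

# Brute-force kNN type-distance oracle: full all-pairs distance matrix and a
# complete sort, no partial selection.
oracle_knn_profiles <- function(map, source_type, k) {
  src <- map[map$cell_type == source_type, ]
  types <- sort(unique(map$cell_type))
  out <- matrix(NA_real_, nrow(src), length(types),
                dimnames = list(src$cell_id, types))
  for (i in seq_len(nrow(src))) {
    d <- sqrt((map$x - src$x[i])^2 + (map$y - src$y[i])^2)
    for (t in types) {
      sel <- map$cell_type == t & map$cell_id != src$cell_id[i]
      dd <- sort(d[sel])
      if (length(dd) >= k) out[i, t] <- mean(dd[seq_len(k)])
    }
  }
  out
}

# Uniform (complete spatial randomness) map with equal counts per type.
csr_map <- function(n_per_type, types, window = c(0, 500, 0, 500), seed = 1) {
  set.seed(seed)
  n <- n_per_type * length(types)
  data.frame(cell_id = sprintf("u%04d", seq_len(n)),
             x = runif(n, window[1], window[2]),
             y = runif(n, window[3], window[4]),
             cell_type = rep(types, each = n_per_type),
             stringsAsFactors = FALSE)
}

# Canonical form of an hclust merge matrix for topology comparison.
canonical_merge <- function(h) {
  m <- h$merge
  t(apply(m, 1, function(r) sort(r)))
}
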