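test_that("frequency tables are exact proportions per unit", {
  ft <- cluster_frequency_table(c("A", "A", "B", "B", "B"), rep("u1", 5))
  expect_equal(unname(ft$values[, "u1"]), c(0.4, 0.6))
  sim <- simulate_cluster_frequencies(5, c(A = 0.5, B = 0.3, C = 0.2),
                                      cells_per_unit = 300, seed = 2)
  expect_true(all(abs(colSums(sim$freq$values) - 1) < 1e-12))
  # realized proportions deviate from the pre-multinomial probabilities by
  # at most 3 binomial sigmas (oracle on the sampling step)
  sig <- sqrt(sim$expected * (1 - sim$expected) / 300)
  expect_true(all(abs(sim$freq$values - sim$expected) < 3 * sig + 1e-9))
})

test_that("correlation distance has the documented structure", {
  v <- matrix(c(0.2, 0.3, 0.25, 0.2, 0.3, 0.25, 0.6, 0.4, 0.5), 3,
              byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("u", 1:3)))
  ft <- freq_table(sweep(v, 2, colSums(v), "/"),
                   data.frame(unit = paste0("u", 1:3)))
  fc <- frequency_correlation(ft)
  expect_equal(fc$r["a", "b"], 1)           # identical rows
  expect_equal(fc$d["a", "b"], 0)
  expect_true(all(fc$d >= 0 & fc$d <= 2))
  expect_true(all(diag(fc$d) == 0))
  # two complementary clusters: r = -1, d = 2
  w <- matrix(c(0.3, 0.5, 0.4, 0.7, 0.5, 0.6), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), paste0("u", 1:3)))
  fc2 <- frequency_correlation(freq_table(w, data.frame(unit = paste0("u", 1:3))))
  expect_equal(fc2$r["x", "y"], -1)
  expect_equal(fc2$d["x", "y"], 2)
  # zero-variance row handled as r = 0 with a message
  z <- matrix(c(0.5, 0.5, 0.5, 0.2, 0.3, 0.1, 0.3, 0.2, 0.4), 3,
              byrow = TRUE,
              dimnames = list(c("flat", "p", "q"), paste0("u", 1:3)))
  expect_message(fc3 <- frequency_correlation(
    freq_table(z, data.frame(unit = paste0("u", 1:3)))), "zero-variance")
  expect_equal(fc3$r["flat", "p"], 0)
  expect_error(frequency_correlation(
    freq_table(z[, 1:2], data.frame(unit = paste0("u", 1:2)))), "3 sample")
})

test_that("ward.D linkage reproduces hand-derived merges", {
  # two leaves: single merge at the supplied dissimilarity
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2)
  t2 <- ward_d_linkage(d2)
  expect_equal(t2$height, 0.3)
  # 4 leaves, two tight blocks: blocks merge first, then each other
  d4 <- matrix(1, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0.1
  d4[3, 4] <- d4[4, 3] <- 0.1
  diag(d4) <- 0
  t4 <- ward_d_linkage(d4)
  expect_equal(t4$height[1:2], c(0.1, 0.1))
  expect_equal(sort(t4$merge[1, ]), c(-2, -1))
  expect_equal(sort(t4$merge[2, ]), c(-4, -3))
  expect_equal(sort(t4$merge[3, ]), c(1, 2))
  # Lance-Williams by hand for the final height: after merging {1,2},
  # d({1,2},3) = d({1,2},4) = (2*1 + 2*1 - 1*0.1)/3; merging {3,4} then gives
  # d({1,2},{3,4}) = [(1+2)*1.3 + (1+2)*1.3 - 2*0.1]/(1+1+2)
  d12_3 <- (2 * 1 + 2 * 1 - 0.1) / 3
  expect_equal(t4$height[3], (3 * d12_3 + 3 * d12_3 - 2 * 0.1) / 4)
  expect_error(ward_d_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(ward_d_linkage(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("ward.D and ward.D2 dialects match the reference implementation", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:10, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    mine <- ward_d_linkage(m)
    ref <- hclust(as.dist(m), method = "ward.D")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    expect_equal(canonical_merge(mine), canonical_merge(ref))
    mine2 <- ward_d_linkage(m, dialect = "ward.D2")
    ref2 <- hclust(as.dist(m), method = "ward.D2")
    expect_equal(mine2$height, ref2$height, tolerance = 1e-12)
    expect_equal(canonical_merge(mine2), canonical_merge(ref2))
  }
})

test_that("cutting the tree yields nested, deterministic partitions", {
  set.seed(77)
  m <- matrix(runif(64), 8)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- letters[1:8]
  tree <- ward_d_linkage(m)
  expect_equal(unname(cut_modules(tree, 8)), 1:8)        # singletons
  expect_true(all(cut_modules(tree, 1) == 1))            # one module
  expect_error(cut_modules(tree, 9), "between")
  # refinement: the k+1 partition never merges what the k partition splits
  for (k in 1:7) {
    a <- cut_modules(tree, k)
    b <- cut_modules(tree, k + 1)
    tab <- table(b, a)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("planted two-module structure is recovered exactly across seeds", {
  base <- rep(1 / 8, 8)
  names(base) <- paste0("c", 1:8)
  L <- matrix(0, 8, 2, dimnames = list(names(base), NULL))
  L[1:4, 1] <- 1
  L[5:8, 2] <- 1
  truth <- rep(1:2, each = 4)
  hits <- 0
  within_r <- numeric(0)
  between_r <- numeric(0)
  for (s in 1:100) {
    f <- simulate_cluster_frequencies(42, base, L, cells_per_unit = 500,
                                      seed = 3000 + s)
    fc <- frequency_correlation(f$freq)
    mods <- cut_modules(ward_d_linkage(fc$d), 2)
    if (isTRUE(all.equal(ari(mods, truth), 1))) hits <- hits + 1
    within_r <- c(within_r, mean(fc$r[1:4, 1:4][upper.tri(diag(4))]))
    between_r <- c(between_r, mean(fc$r[1:4, 5:8]))
  }
  expect_gte(hits, 95)
  # planted covariation: within-module correlation exceeds between-module
  expect_gt(mean(within_r), mean(between_r))
})

test_that("the rank-sum engine is exact and matches the reference test", {
  t0 <- rank_sum_test(1:3, 4:6)
  expect_equal(t0$p.value, 0.1)
  expect_equal(t0$method, "exact")
  # cross-check both paths against the reference implementation
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(sample(4:9, 1))
    y <- rnorm(sample(4:9, 1), 0.8)
    expect_equal(rank_sum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    # the moment-corrected path against the reference exact computation
    x2 <- rnorm(15); y2 <- rnorm(18, 0.5)
    expect_lt(abs(rank_sum_test(x2, y2)$p.value -
                    wilcox.test(x2, y2, exact = TRUE)$p.value), 0.005)
  }
})

test_that("the moment-corrected approximation tracks enumeration closely", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    n1 <- sample(8:10, 1)
    n2 <- sample(8:10, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, 0.5)
    pe <- rank_sum_test(x, y)$p.value
    pn <- rank_sum_test(x, y, exact_max = 0)$p.value
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.005)
})

test_that("module markers recover planted cluster-specific genes", {
  sim <- suppressWarnings(  # planted-fraction clipping is expected
    simulate_cohort(cohort_sim_config(n_individuals = 6,
                                      cells_per_individual = 300,
                                      seed = 41)))
  qc <- qc_filter(sim$expr)
  # two modules: epithelial+LPC vs the rest (clusters are the true types)
  cls <- sort(unique(qc$expr$cell_meta$cluster))
  mods <- ifelse(cls %in% c("hepatocyte", "cholangiocyte", "LPC"), 1L, 2L)
  names(mods) <- cls
  mk <- module_markers(qc$expr, mods)
  expect_true(all(c("ALB", "PCK1") %in% mk$top[["1"]]))
  expect_true(all(c("CD3D", "CD68") %in% mk$top[["2"]]))
  expect_false(any(c("ALB", "PCK1") %in% mk$top[["2"]]))
  tab <- mk$table
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  expect_true(all(tab$frac_in >= 0 & tab$frac_in <= 1))
  # a flat gene has zero fold-change and p 1
  m <- matrix(3, 10, 5)
  ex <- make_expr(m, cluster = rep(c("a", "b"), each = 5))
  mk2 <- module_markers(ex, c(a = 1L, b = 2L), min_cells = 3)
  expect_true(all(mk2$table$log2fc == 0))
  expect_true(all(mk2$table$p == 1))
})

test_that("BH adjustment is monotone after sorting raw p", {
  set.seed(4)
  p <- runif(200)^2
  adj <- p.adjust(sort(p), method = "BH")
  expect_true(all(diff(adj) >= -1e-15))
})

test_that("fraction expressing separates planted markers by module", {
  sim <- simulate_cohort(cohort_sim_config(n_individuals = 4,
                                           cells_per_individual = 250,
                                           seed = 43))
  cls <- sort(unique(sim$expr$cell_meta$cluster))
  mods <- ifelse(cls == "T_cell", 1L, 2L)
  names(mods) <- cls
  fr <- fraction_expressing(sim$expr, list(tmark = c("CD3D", "CD3E")), mods)
  own <- fr$frac_in[fr$module == 1]
  other <- fr$frac_in[fr$module == 2]
  expect_gt(own, other)
  # a gene expressed everywhere has fraction 1 in every module
  m <- matrix(1, 6, 3)
  ex <- make_expr(m, cluster = rep(c("a", "b"), 3))
  fr2 <- fraction_expressing(ex, list(all = c("g001")), c(a = 1L, b = 2L))
  expect_true(all(fr2$frac_in == 1))
  expect_error(fraction_expressing(ex, list(bad = character(0)),
                                   c(a = 1L, b = 2L)), "nonempty")
})
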