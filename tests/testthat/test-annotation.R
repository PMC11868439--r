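test_that("cluster z-scores match the hand formula and a dense oracle", {
  # two clusters: any gene with distinct means gets z = (-0.7071, +0.7071)
  m <- matrix(0, 6, 5)
  m[4:6, 1] <- 8          # gene 1 only in cluster B
  m[, 2] <- 3             # flat gene
  m[1:3, 3] <- 2; m[4:6, 3] <- 6
  m[, 4:5] <- 1
  ex <- make_expr(m, cluster = rep(c("A", "B"), each = 3))
  z <- cluster_mean_zscores(ex)
  expect_equal(unname(z$z["g001", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z$z["g003", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # rows are standardized: mean 0, sample sd 1 (or all zero)
  expect_true(all(abs(rowMeans(z$z)) < 1e-12))
  sds <- apply(z$z, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-12 | sds == 0))
  expect_error(cluster_mean_zscores(ex, clusters = rep("A", 6)),
               "at least 2")
})

test_that("z-scores equal a from-scratch dense recomputation", {
  set.seed(8)
  m <- matrix(rpois(40 * 20, 4), 40, 20)
  cl <- sample(c("x", "y", "z"), 40, replace = TRUE)
  ex <- make_expr(m, cluster = cl)
  z <- cluster_mean_zscores(ex)
  # oracle: dense log-normalization and explicit per-gene standardization
  ln <- log1p(m / rowSums(m) * 1e4)
  for (g in seq_len(20)) {
    mg <- as.numeric(tapply(ln[, g], cl, mean)[colnames(z$z)])
    zg <- if (sd(mg) == 0) rep(0, length(mg)) else (mg - mean(mg)) / sd(mg)
    expect_equal(as.numeric(z$z[g, ]), zg, tolerance = 1e-10)
  }
})

test_that("cluster labels follow the panel argmax with threshold and ties", {
  z <- structure(list(z = matrix(c(2, -1, -1, 2), 2, 2,
                                 dimnames = list(c("PCK1", "SOX9"),
                                                 c("k1", "k2")))),
                 class = "zscore_matrix")
  panels <- list(hepatocyte = "PCK1", cholangiocyte = "SOX9")
  a <- assign_cell_types(z, panels, min_z = 0, exclude = character(0))
  expect_equal(unname(a$assignment), c("hepatocyte", "cholangiocyte"))
  # below threshold: unassigned
  a2 <- assign_cell_types(z, panels, min_z = 3, exclude = character(0))
  expect_true(all(a2$assignment == "unassigned"))
  # exact tie broken by panel name order (first panel wins)
  zt <- structure(list(z = matrix(c(1, 1), 2, 1,
                                  dimnames = list(c("PCK1", "SOX9"), "k1"))),
                  class = "zscore_matrix")
  at <- assign_cell_types(zt, panels, min_z = 0, exclude = character(0))
  expect_equal(unname(at$assignment), "hepatocyte")
  expect_error(assign_cell_types(z, list(hepatocyte = "ABSENT"),
                                 exclude = character(0)), "no genes")
})

test_that("LPC flags require all three panels and are monotone in tau", {
  sim <- simulate_cohort(cohort_sim_config(n_individuals = 6,
                                           cells_per_individual = 300,
                                           seed = 17))
  qc <- qc_filter(sim$expr)
  z <- cluster_mean_zscores(qc$expr)
  flags <- identify_lpc_clusters(z, tau = 0.5)
  expect_true(flags[["LPC"]])
  expect_false(any(flags[setdiff(names(flags), "LPC")]))
  # all-zero z matrix: nothing flagged at tau 0.5; everything at tau = -Inf
  z0 <- z; z0$z[] <- 0
  expect_false(any(identify_lpc_clusters(z0, tau = 0.5)))
  expect_true(all(identify_lpc_clusters(z0, tau = -Inf)))
  # monotone non-increasing flag sets as tau grows
  prev <- rep(TRUE, length(flags))
  for (tau in c(-2, 0, 0.5, 1, 3)) {
    cur <- identify_lpc_clusters(z, tau = tau)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("annotation recovers the planted types", {
  sim <- simulate_cohort(cohort_sim_config(n_individuals = 8,
                                           cells_per_individual = 300,
                                           seed = 23))
  qc <- qc_filter(sim$expr)
  ann <- annotate_cohort(qc$expr)
  agree <- mean(ann$cell_type == qc$expr$cell_meta$true_type)
  expect_gte(agree, 0.95)
})

test_that("module score is zero on flat cells and null for random sets", {
  m <- matrix(5, 8, 40)
  ex <- make_expr(m)
  s <- score_gene_module(ex, colnames(ex$counts)[1:4], seed = 1)
  expect_equal(s, rep(0, 8))
  # random set over many control draws: mean score concentrates at 0
  set.seed(31)
  m2 <- matrix(rpois(30 * 120, 5), 30, 120)
  ex2 <- make_expr(m2)
  means <- sapply(1:50, function(s) {
    mean(score_gene_module(ex2, colnames(ex2$counts), n_ctrl = 100, seed = s))
  })
  expect_lt(abs(mean(means)), 0.01)
  expect_error(score_gene_module(ex2, c("nope1", "nope2")), "absent")
})

test_that("module score is invariant to cell order", {
  set.seed(5)
  m <- matrix(rpois(20 * 60, 4), 20, 60)
  ex <- make_expr(m)
  set_genes <- colnames(ex$counts)[5:10]
  s1 <- score_gene_module(ex, set_genes, seed = 3)
  perm <- sample(20)
  s2 <- score_gene_module(ex[perm, ], set_genes, seed = 3)
  expect_equal(s1[perm], s2, tolerance = 1e-12)
})

test_that("planted LPCs outscore hepatocytes on the regeneration set", {
  sim <- suppressWarnings(  # planted-fraction clipping is expected
    simulate_cohort(cohort_sim_config(n_individuals = 8,
                                      cells_per_individual = 400,
                                      seed = 29)))
  qc <- qc_filter(sim$expr)
  s <- score_gene_module(qc$expr, regeneration_gene_set(), seed = 11)
  tt <- qc$expr$cell_meta$true_type
  expect_gt(median(s[tt == "LPC"]), median(s[tt == "hepatocyte"]))
})

test_that("LPC proportions are plain arithmetic with clean edge handling", {
  types <- c(rep("LPC", 3), rep("hepatocyte", 80), rep("cholangiocyte", 17),
             rep("T_cell", 50))
  p <- lpc_proportions(types, rep("i1", 150))
  expect_equal(p$per_individual$proportion, 0.03)  # 3 of 100 epi+LPC
  # T cells are outside the denominator entirely
  expect_equal(p$per_individual$n_epi_lpc, 100)
  # identical individuals: sd 0
  p2 <- lpc_proportions(rep(types, 3), rep(c("a", "b", "c"), each = 150))
  expect_equal(p2$sd, 0)
  expect_equal(p2$mean, 0.03)
  # an individual with no epithelial or LPC cells is excluded, with a note
  expect_message(
    p3 <- lpc_proportions(c(types, rep("T_cell", 5)),
                          c(rep("i1", 150), rep("i2", 5))),
    "excluding")
  expect_equal(p3$n, 1)
})

test_that("group comparisons reuse the rank-sum engine", {
  types <- c(rep("LPC", 2), rep("hepatocyte", 98))
  inds <- sprintf("i%02d", 1:8)
  cell_types <- rep(types, 8)
  individuals <- rep(inds, each = 100)
  # plant a higher proportion in every individual of the second group
  for (i in 5:8) cell_types[(i - 1) * 100 + 1:40] <- "LPC"
  p <- lpc_proportions(cell_types, individuals,
                       groups = list(g1 = inds[1:4], g2 = inds[5:8]))
  expect_named(p$tests, "g1_vs_g2")
  expect_lt(p$tests$g1_vs_g2, 0.05)
})
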