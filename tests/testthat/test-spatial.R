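test_that("kNN distance profiles follow forced-neighbour arithmetic", {
  map <- data.frame(
    cell_id = c("L1", paste0("C", 1:5)),
    x = c(0, 1, 2, 3, 4, 5), y = 0,
    cell_type = c("LPC", rep("cholangiocyte", 5)),
    stringsAsFactors = FALSE)
  p <- knn_type_distance_profiles(map, "LPC", k = 4)
  expect_equal(unname(p$profiles["L1", "cholangiocyte"]), 2.5)  # (1+2+3+4)/4
  # k = 1 on two cells: the plain Euclidean distance
  map2 <- data.frame(cell_id = c("a", "b"), x = c(0, 3), y = c(0, 4),
                     cell_type = c("LPC", "hepatocyte"))
  p2 <- knn_type_distance_profiles(map2, "LPC", k = 1)
  expect_equal(unname(p2$profiles["a", "hepatocyte"]), 5)
  # too few cells of a type: NA, never zero; self-type excludes the source
  expect_true(is.na(p2$profiles["a", "LPC"]))
  expect_error(knn_type_distance_profiles(map2, "absent"), "absent")
})

test_that("profiles equal the all-pairs brute-force oracle", {
  set.seed(12)
  map <- csr_map(60, c("LPC", "cholangiocyte", "hepatocyte", "HSC",
                       "endothelial"), seed = 12)
  p <- knn_type_distance_profiles(map, "LPC", k = 4)
  expect_equal(p$profiles, oracle_knn_profiles(map, "LPC", 4),
               tolerance = 1e-12)
})

test_that("profiles are rigid-motion invariant and monotone in k", {
  map <- csr_map(30, c("LPC", "cholangiocyte", "hepatocyte"), seed = 7)
  p1 <- knn_type_distance_profiles(map, "LPC", k = 3)$profiles
  th <- 0.7
  rot <- map
  rot$x <- cos(th) * map$x - sin(th) * map$y + 100
  rot$y <- sin(th) * map$x + cos(th) * map$y - 50
  p2 <- knn_type_distance_profiles(rot, "LPC", k = 3)$profiles
  expect_equal(p1, p2, tolerance = 1e-9)
  for (k in 1:4) {
    a <- knn_type_distance_profiles(map, "LPC", k = k)$profiles
    b <- knn_type_distance_profiles(map, "LPC", k = k + 1)$profiles
    expect_true(all(b >= a - 1e-12, na.rm = TRUE))
  }
})

test_that("colocalization ranking orders types by median distance", {
  m <- simulate_spatial(spatial_sim_config(seed = 51))
  p <- knn_type_distance_profiles(m, "LPC", k = 4)
  rk <- rank_colocalization(p)
  expect_equal(rk$cell_type[1], "cholangiocyte")
  expect_true(all(diff(rk$median) >= 0))
  # single-type map ranks trivially
  one <- data.frame(cell_id = paste0("c", 1:6),
                    x = runif(6), y = runif(6), cell_type = "LPC")
  rk1 <- rank_colocalization(knn_type_distance_profiles(one, "LPC", k = 2))
  expect_equal(nrow(rk1), 1)
})

test_that("profile clustering separates planted attracted vs roaming LPCs", {
  hits <- 0
  for (s in 1:50) {
    set.seed(6000 + s)
    # one cholangiocyte hotspot plus background types
    n_c <- 40
    cho <- data.frame(cell_id = sprintf("c%03d", 1:n_c),
                      x = rnorm(n_c, 100, 10), y = rnorm(n_c, 100, 10),
                      cell_type = "cholangiocyte")
    hep <- data.frame(cell_id = sprintf("h%03d", 1:150),
                      x = runif(150, 0, 500), y = runif(150, 0, 500),
                      cell_type = "hepatocyte")
    near <- data.frame(cell_id = sprintf("ln%02d", 1:15),
                       x = rnorm(15, 100, 12), y = rnorm(15, 100, 12),
                       cell_type = "LPC")
    far <- data.frame(cell_id = sprintf("lf%02d", 1:15),
                      x = runif(15, 250, 500), y = runif(15, 250, 500),
                      cell_type = "LPC")
    map <- rbind(cho, hep, near, far)
    p <- knn_type_distance_profiles(map, "LPC", k = 4)
    grp <- cluster_distance_profiles(p, 2)$groups
    truth <- rep(1:2, each = 15)
    if (ari(grp, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 45)
  # degenerate input: identical rows co-assign at k_groups = 1
  pp <- structure(list(profiles = matrix(1, 4, 2,
                                         dimnames = list(paste0("l", 1:4),
                                                         c("a", "b"))),
                       k = 1, source_type = "LPC", raw = list()),
                  class = "distance_profiles")
  expect_true(all(cluster_distance_profiles(pp, 1)$groups == 1))
  expect_error(cluster_distance_profiles(pp, 9), "fewer")
})

test_that("pseudo-bulk profiles are scale-invariant count aggregates", {
  set.seed(3)
  m <- matrix(rpois(12 * 40, 5), 12, 40)
  ex <- make_expr(m)
  # single cell: equals that cell's own CPM-log transform
  p1 <- pseudobulk_profile(ex, 1)
  expect_equal(unname(p1$log_cpm), log1p(m[1, ] / sum(m[1, ]) * 1e6))
  # doubling all counts changes nothing
  ex2 <- make_expr(2 * m)
  expect_equal(pseudobulk_profile(ex)$log_cpm, pseudobulk_profile(ex2)$log_cpm)
  # two disjoint halves merge to the whole (count-sum oracle)
  whole <- pseudobulk_profile(ex)
  sums <- colSums(m[1:6, ]) + colSums(m[7:12, ])
  expect_equal(unname(whole$log_cpm), log1p(sums / sum(sums) * 1e6))
  expect_error(pseudobulk_profile(ex, integer(0)), "empty")
})

test_that("pseudo-bulk correlation behaves at its extremes and on replicates", {
  set.seed(9)
  m <- matrix(rpois(10 * 30, 6), 10, 30)
  ex <- make_expr(m)
  a <- pseudobulk_profile(ex)
  expect_equal(pseudobulk_correlation(a, a), 1)
  neg <- a
  neg$log_cpm <- 2 * mean(a$log_cpm) - a$log_cpm  # reflect about the mean
  expect_equal(pseudobulk_correlation(a, neg), -1)
  flat <- a
  flat$log_cpm[] <- 1
  expect_error(pseudobulk_correlation(a, flat), "zero-variance")
  # independent cohorts from identical LPC parameters agree strongly
  s1 <- simulate_cohort(cohort_sim_config(n_individuals = 4,
                                          cells_per_individual = 400,
                                          seed = 61))
  s2 <- simulate_cohort(cohort_sim_config(n_individuals = 4,
                                          cells_per_individual = 400,
                                          seed = 62))
  l1 <- pseudobulk_profile(s1$expr, s1$expr$cell_meta$true_type == "LPC")
  l2 <- pseudobulk_profile(s2$expr, s2$expr$cell_meta$true_type == "LPC")
  expect_gt(pseudobulk_correlation(l1, l2), 0.9)
})
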