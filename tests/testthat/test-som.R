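test_that("dispersion filter excludes stable profiles (population SD)", {
  v <- rbind(
    flat = c(5, 5, 5),          # dispersion 0: excluded
    mild = c(10, 10.5, 11),     # SD/mean ~ 0.04: excluded
    dyn  = c(1, 3, 1)           # handled below
  )
  colnames(v) <- paste0("S", 1:3)
  out <- dispersion_filter(grn_expr(v), cutoff = 0.2)
  expect_setequal(out$excluded, c("flat", "mild"))
  expect_equal(out$included, "dyn")
  expect_equal(unname(out$dispersion["flat"]), 0)
  # two-point worked case: population SD of (1,3) is 1, mean 2 -> 0.5
  v2 <- rbind(g = c(1, 3)); colnames(v2) <- c("S1", "S2")
  out2 <- dispersion_filter(grn_expr(v2), cutoff = 0.2)
  expect_equal(unname(out2$dispersion["g"]), 0.5)
  expect_equal(out2$included, "g")
  # included + excluded covers all genes
  expect_setequal(c(out$included, out$excluded), rownames(v))
  # zero-mean profile excluded with a message
  v3 <- rbind(z = c(0, 0, 0), g = c(1, 3, 9)); colnames(v3) <- paste0("S", 1:3)
  expect_message(out3 <- dispersion_filter(grn_expr(v3)), "nonpositive")
  expect_true("z" %in% out3$excluded)
})

test_that("identical profiles always co-cluster; anti-correlated ones rarely do", {
  set.seed(1)
  base <- runif(9)
  v <- rbind(
    a = base, b = base,                      # byte-identical pair
    anti1 = rep(c(0, 1), length.out = 9),
    anti2 = rep(c(1, 0), length.out = 9),
    r1 = runif(9), r2 = runif(9)
  )
  colnames(v) <- paste0("S", 1:9)
  m <- grn_expr(v, scaled = TRUE)
  cc <- co_cluster(m, n_runs = 60, grid_min = 2, grid_max = 3, seed = 42)
  expect_equal(cc$coincidence["a", "b"], 1)
  expect_lt(cc$coincidence["anti1", "anti2"], 0.2)
})

test_that("coincidence matrix is symmetric, unit diagonal, multiples of 1/n_runs", {
  set.seed(3)
  v <- matrix(runif(8 * 9), 8, 9,
              dimnames = list(paste0("g", 1:8), paste0("S", 1:9)))
  cc <- co_cluster(grn_expr(v, scaled = TRUE), n_runs = 25, grid_min = 2,
                   grid_max = 4, seed = 7)
  expect_identical(cc$coincidence, t(cc$coincidence))
  expect_equal(unname(diag(cc$coincidence)), rep(1, 8))
  expect_true(all(abs(cc$coincidence * 25 - round(cc$coincidence * 25)) < 1e-9))
})

test_that("co_cluster is deterministic under a fixed seed", {
  v <- matrix(runif(6 * 9), 6, 9,
              dimnames = list(paste0("g", 1:6), paste0("S", 1:9)))
  m <- grn_expr(v, scaled = TRUE)
  c1 <- co_cluster(m, n_runs = 10, grid_min = 2, grid_max = 4, seed = 5)
  c2 <- co_cluster(m, n_runs = 10, grid_min = 2, grid_max = 4, seed = 5)
  expect_identical(c1$coincidence, c2$coincidence)
})

test_that("partition: components at threshold, boundary cases, monotone splits", {
  part <- toy_partition()
  expect_setequal(lapply(part$clusters, sort),
                  list(c("A", "B", "C"), c("D", "E"), "F"))
  expect_equal(part$singleton_count, 1L)
  # threshold above all off-diagonal coincidences: all singletons
  cc <- structure(list(genes = c("x", "y"),
                       coincidence = matrix(c(1, 0.5, 0.5, 1), 2,
                                            dimnames = list(c("x", "y"), c("x", "y"))),
                       n_runs = 10L), class = "grn_coclust")
  expect_equal(lengths(partition_clusters(cc, 0.9)$clusters), c(1L, 1L))
  # threshold below everything: one cluster
  expect_equal(lengths(partition_clusters(cc, 0.1)$clusters), 2L)
  # monotone: raising the threshold only splits, never merges
  set.seed(8)
  n <- 10
  co <- matrix(runif(n * n), n); co <- (co + t(co)) / 2; diag(co) <- 1
  dimnames(co) <- list(paste0("g", 1:n), paste0("g", 1:n))
  cc2 <- structure(list(genes = rownames(co), coincidence = co, n_runs = 10L),
                   class = "grn_coclust")
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    lo <- partition_clusters(cc2, th)
    hi <- partition_clusters(cc2, min(th + 0.2, 1))
    for (cl in hi$clusters) {
      # every high-threshold cluster sits inside one low-threshold cluster
      host <- lo$membership[cl]
      expect_equal(length(unique(host)), 1L)
    }
  }
})

test_that("cluster product multiplies endpoint cluster sizes", {
  part <- toy_partition()
  expect_equal(cluster_product("A", "D", part), 6L)   # 3 x 2
  expect_equal(cluster_product("F", "F", part), 1L)   # singleton-singleton
  expect_equal(cluster_product("A", "B", part), 9L)   # within-cluster, 3 x 3
  # symmetric under edge reversal; unknown genes count as singletons
  expect_equal(cluster_product("D", "A", part), cluster_product("A", "D", part))
  expect_equal(cluster_product("Z9", "A", part), 3L)
})

test_that("planted near-identical modules co-cluster at threshold 0.7", {
  # grids are kept crowded (several genes per unit), matching the
  # genes-per-unit regime the co-clustering is designed for; occasional
  # splits remain possible because several units can converge onto the
  # module (the densest point mass), so the property is asserted over seeds
  single <- logical(10)
  mean_co <- numeric(10)
  for (seed in 1:10) {
    ds <- make_synthetic_dataset(n_genes = 15, mean_degree = 1.5,
                                 module_sizes = 5, noise_sd = 0.02,
                                 seed = seed)
    cc <- co_cluster(ds$expression, n_runs = 60, grid_min = 2, grid_max = 3,
                     seed = seed)
    part <- partition_clusters(cc, 0.7)
    mod <- ds$modules[[1]]
    single[seed] <- length(unique(part$membership[mod])) == 1L
    co <- cc$coincidence[mod, mod]
    mean_co[seed] <- mean(co[upper.tri(co)])
  }
  expect_gte(sum(single), 8)
  expect_gt(mean(mean_co), 0.7)
})
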