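test_that("clustering coefficient handles canonical fixtures", {
  # triangle with equal weights: every node fully clustered
  tri <- wmat(3, list(c(1, 2, 0.5), c(2, 3, 0.5), c(1, 3, 0.5)))
  cc <- clustering_coefficient(tri)
  expect_equal(unname(cc$nodal), rep(1, 3))
  expect_equal(cc$cp, 1)

  # 3-node path: no triangles
  path <- wmat(3, list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(clustering_coefficient(path)$cp, 0)

  # 4-node fixture with one weighted triangle: direct enumeration
  w <- wmat(4, list(c(1, 2, 0.9), c(1, 3, 0.6), c(2, 3, 0.3), c(3, 4, 0.5)))
  cc4 <- clustering_coefficient(w)$nodal
  expect_equal(unname(cc4), oracle_clustering(w))
})

test_that("path length uses inverse-weight distances", {
  # 3-node unit path: distances 1, 1, 2 -> Lp = 4/3
  path <- wmat(3, list(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(characteristic_path_length(path)$lp, 4 / 3)

  # weak edge rerouted through the strong third node: 1/1 + 1/1 < 1/0.25
  tri <- wmat(3, list(c(1, 2, 1), c(2, 3, 1), c(1, 3, 0.25)))
  d <- characteristic_path_length(tri)$distances
  expect_equal(d[1, 3], 2)
})

test_that("degree and betweenness match closed forms", {
  star <- wmat(6, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1),
                       c(1, 6, 1)))
  deg <- nodal_degree(star)
  expect_equal(unname(deg), c(5, 1, 1, 1, 1, 1))
  bc <- betweenness_centrality(star)
  expect_equal(unname(bc[1]), 5 * 4 / 2) # (n-1)(n-2)/2 on unordered pairs
  expect_equal(unname(bc[-1]), rep(0, 5))

  # 4-cycle: two tied shortest paths split the count -> 0.5 each
  cyc <- wmat(4, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 4, 1)))
  expect_equal(unname(betweenness_centrality(cyc)), rep(0.5, 4))

  # handshake lemma on random graphs
  set.seed(31)
  for (i in 1:25) {
    w <- random_connected_graph(8)
    expect_equal(sum(nodal_degree(w)), 2 * sum(w[upper.tri(w)] > 0))
  }
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    w <- random_connected_graph(n, wset = NULL)
    expect_equal(unname(clustering_coefficient(w)$nodal),
                 oracle_clustering(w))
    expect_equal(unname(characteristic_path_length(w)$distances),
                 unname(oracle_distances(w)))
    expect_equal(unname(betweenness_centrality(w)), oracle_betweenness(w),
                 tolerance = 1e-12)
  }
})

test_that("weight scaling behaves as the formulas dictate", {
  set.seed(33)
  w <- random_connected_graph(7)
  for (c_scale in c(0.3, 0.8, 1)) {
    ws <- w * c_scale
    expect_equal(nodal_degree(ws), nodal_degree(w))
    expect_equal(betweenness_centrality(ws), betweenness_centrality(w))
    expect_equal(characteristic_path_length(ws)$lp,
                 characteristic_path_length(w)$lp / c_scale)
    expect_equal(clustering_coefficient(ws)$cp,
                 clustering_coefficient(w)$cp)
  }
})

test_that("rewiring preserves the degree sequence and weight multiset", {
  set.seed(34)
  w <- random_connected_graph(10, wset = NULL, p_edge = 0.4)
  deg0 <- nodal_degree(w)
  weights0 <- sort(w[upper.tri(w) & w > 0])
  for (i in 1:50) {
    null <- maslov_sneppen_rewire(w, seed = i)
    expect_identical(nodal_degree(null), deg0)
    expect_equal(sort(null[upper.tri(null) & null > 0]), weights0)
  }
  # determinism: same seed, same null
  expect_identical(maslov_sneppen_rewire(w, seed = 7),
                   maslov_sneppen_rewire(w, seed = 7))
  # a triangle can only be rewired to itself
  tri <- wmat(3, list(c(1, 2, 0.9), c(2, 3, 0.8), c(1, 3, 0.7)))
  null_tri <- maslov_sneppen_rewire(tri, seed = 1)
  expect_equal(nodal_degree(null_tri), nodal_degree(tri))
  expect_setequal(null_tri[upper.tri(null_tri)], tri[upper.tri(tri)])
})

test_that("self-ensemble normalization returns exactly 1", {
  set.seed(35)
  w <- random_connected_graph(8)
  cp <- clustering_coefficient(w)$cp
  lp <- characteristic_path_length(w)$lp
  ens <- structure(list(cp = rep(cp, 10), lp = rep(lp, 10),
                        mean_null_cp = cp, mean_null_lp = lp,
                        n_nulls = 10), class = "null_ensemble")
  nm <- normalized_metrics(w, ens)
  expect_equal(nm$gamma, 1)
  expect_equal(nm$lambda, 1)
  expect_equal(nm$sigma, 1)
})

test_that("modular networks show the small-world signature gamma > 1", {
  # high-clustering fixture: dense modules, sparse bridges
  spec <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 20,
                      n_timepoints = 200, n_modules = 4,
                      within_module_corr_a = 0.7, within_module_corr_b = 0.7,
                      between_module_corr = 0.05, subject_corr_sd = 0,
                      seed = 12)
  s <- simulate_subject(spec, "A", 55)
  net <- threshold_with_mst(pearson_connectivity(s$series), 0.25)
  ens <- null_ensemble(net, n_nulls = 200, seed = 3)
  nm <- normalized_metrics(net, ens)
  expect_gt(nm$gamma, 1)
  expect_gt(nm$sigma, 1)
})

test_that("null ensemble means are Monte-Carlo stable", {
  spec <- cohort_spec(n_group_a = 2, n_group_b = 2, seed = 13)
  s <- simulate_subject(spec, "B", 77)
  net <- threshold_with_mst(pearson_connectivity(s$series), 0.2)
  ens500 <- null_ensemble(net, n_nulls = 500, seed = 41)
  ens1000 <- null_ensemble(net, n_nulls = 1000, seed = 42)
  nm500 <- normalized_metrics(net, ens500)
  nm1000 <- normalized_metrics(net, ens1000)
  expect_lt(abs(nm500$gamma / nm1000$gamma - 1), 0.02)
  expect_lt(abs(nm500$lambda / nm1000$lambda - 1), 0.02)
})

test_that("AUC is the trapezoidal integral with its closed forms", {
  grid <- sparsity_grid()
  expect_equal(auc_over_grid(rep(3, 29), grid), 0.28 * 3)
  expect_equal(auc_over_grid(seq(0, 1, length.out = 29), grid), 0.14)
  # numeric oracle: fine-grained integration of the linear interpolant
  set.seed(36)
  y <- rnorm(29)
  f <- approxfun(as.numeric(grid), y)
  xs <- seq(0.12, 0.40, length.out = 1e5)
  ys <- f(xs)
  oracle <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  expect_equal(auc_over_grid(y, grid), oracle, tolerance = 1e-8)
  # linearity
  y2 <- rnorm(29)
  expect_equal(auc_over_grid(2 * y + 3 * y2, grid),
               2 * auc_over_grid(y, grid) + 3 * auc_over_grid(y2, grid))
  expect_error(auc_over_grid(y[1:5], grid), "length")
})

test_that("subject profiles have full curves, AUCs, and are reproducible", {
  spec <- cohort_spec(n_group_a = 2, n_group_b = 2, seed = 14)
  s <- simulate_subject(spec, "B", 88)
  conn <- pearson_connectivity(s$series)
  p1 <- profile_subject(conn, n_nulls = 30, seed = 9)
  expect_equal(nrow(p1$global), 29)
  expect_length(p1$auc$degree, 28)
  expect_length(p1$auc$betweenness, 28)
  expect_true(all(is.finite(unlist(p1$auc))))
  expect_true(all(p1$global$gamma > 0))
  p2 <- profile_subject(conn, n_nulls = 30, seed = 9)
  expect_identical(p1$global, p2$global)
  expect_identical(p1$auc, p2$auc)
})
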