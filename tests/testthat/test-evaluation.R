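test_that("Gini matches its analytic anchors and the pairwise oracle", {
  expect_equal(gini(rep(3, 50)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  withr::with_seed(1, v <- rexp(1e5))
  expect_equal(gini(v), 0.5, tolerance = 0.005)
  withr::with_seed(2, {
    for (i in 1:100) {
      u <- runif(sample(2:40, 1)) * sample(c(1, 100), 1)
      expect_equal(gini(u), oracle_gini(u), tolerance = 1e-12)
    }
  })
  expect_warning(g <- gini(c(-1, 2, 3)), "floored")
  expect_error(gini(c(0, 0, 0)), "undefined")
})

test_that("spatial footprint reproduces a known distance kernel and its invariances", {
  ids <- paste0("u", 1:20)
  geom <- make_grid_geometry(ids, n_side = 5, seed = 1)
  gx <- setNames(geom$x, geom$unit); gy <- setNames(geom$y, geom$unit)
  D <- outer(seq_along(ids), seq_along(ids), function(i, j)
    sqrt((gx[ids[i]] - gx[ids[j]])^2 + (gy[ids[i]] - gy[ids[j]])^2))
  vals <- exp(-D)
  m <- new_conn_matrix(vals, "test", ids)
  fp <- spatial_footprint(m, geom, bins = 5)
  ok <- !is.na(fp$mean)
  # bin means sit within the exp(-d) envelope of their bin edges
  expect_true(all(fp$mean[ok] <= exp(-fp$d_lo[ok]) + 1e-9))
  expect_true(all(fp$mean[ok] >= exp(-fp$d_hi[ok]) - 1e-9))
  # permuting unit labels together with geometry rows changes nothing
  perm <- withr::with_seed(3, sample(20))
  m2 <- new_conn_matrix(vals[perm, perm], "test", ids[perm])
  fp2 <- spatial_footprint(m2, geom, bins = 5)
  expect_equal(fp$mean, fp2$mean)
  # an all-equal matrix gives a flat curve
  flat <- spatial_footprint(new_conn_matrix(matrix(2, 20, 20), "t", ids),
                            geom, bins = 4)
  expect_true(all(abs(flat$mean[!is.na(flat$mean)] - 2) < 1e-12))
})

test_that("distance residualization removes pure distance structure, keeps offsets out", {
  ids <- paste0("u", 1:20)
  geom <- make_grid_geometry(ids, n_side = 5, seed = 1)
  gx <- setNames(geom$x, geom$unit); gy <- setNames(geom$y, geom$unit)
  D <- outer(seq_along(ids), seq_along(ids), function(i, j)
    sqrt((gx[ids[i]] - gx[ids[j]])^2 + (gy[ids[i]] - gy[ids[j]])^2))
  # a matrix that is a pure (piecewise-constant) function of binned distance
  breaks <- seq(0, max(D) + 1, by = 1)
  vals <- matrix(2 * cut(D, breaks, include.lowest = TRUE, labels = FALSE),
                 nrow(D))
  m <- new_conn_matrix(vals, "t", ids)
  res <- residualize_distance(m, geom, bins = breaks)
  expect_lt(max(abs(res$values), na.rm = TRUE), 1e-9)
  # adding a constant leaves residuals unchanged
  m_shift <- new_conn_matrix(vals + 7, "t", ids)
  res2 <- residualize_distance(m_shift, geom, bins = breaks)
  expect_equal(res$values, res2$values)
})

test_that("prediction tests recover exact and null relations", {
  ids <- paste0("u", 1:8)
  withr::with_seed(4, cf_vals <- matrix(abs(rnorm(64)), 8))
  cf <- new_conn_matrix(cf_vals, "ccm", ids, subclass = "cf_matrix",
                        sig_mask = cf_vals > median(cf_vals))
  ic <- new_conn_matrix(0.5 * cf_vals, "ks", ids, subclass = "ic_matrix")
  rep <- prediction_tests(cf, ic)
  expect_equal(rep$stats$pearson_r, 1, tolerance = 1e-12)
  expect_equal(rep$stats$regression_slope, 0.5, tolerance = 1e-12)
  expect_gt(rep$stats$ic_by_cf_sig$mean_a, rep$stats$ic_by_cf_sig$mean_b)
  # shuffled IC: correlation within the null band, group test insignificant
  hits <- vapply(1:20, function(s) {
    perm <- withr::with_seed(s, sample(64))
    icv <- matrix(as.vector(0.5 * cf_vals)[perm], 8)
    diag(icv) <- NA
    ic_s <- new_conn_matrix(icv, "ks", ids, subclass = "ic_matrix")
    r <- prediction_tests(cf, ic_s)
    c(abs(r$stats$pearson_r) < 2.5 / sqrt(r$stats$n_pairs) + 0.15,
      is.na(r$stats$ic_by_cf_sig$p) || r$stats$ic_by_cf_sig$p > 0.05)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
  # tidy/glance expose the same numbers
  td <- tidy(rep)
  expect_equal(td$estimate[td$statistic == "pearson_r" & td$variant == "raw"],
               1, tolerance = 1e-12)
  expect_equal(glance(rep)$pearson_r, 1, tolerance = 1e-12)
})

test_that("residualized prediction tests run on the same pair set", {
  ids <- paste0("u", 1:12)
  geom <- make_grid_geometry(ids, n_side = 5, seed = 2)
  withr::with_seed(5, cf_vals <- matrix(abs(rnorm(144)), 12))
  cf <- new_conn_matrix(cf_vals, "ccm", ids, subclass = "cf_matrix")
  ic <- new_conn_matrix(0.3 * cf_vals + 0.01, "ks", ids,
                        subclass = "ic_matrix")
  rep <- prediction_tests(cf, ic, geom = geom, bins = 4)
  expect_equal(rep$stats_residual$n_pairs, rep$stats$n_pairs)
  # coupling independent of distance: residual correlation stays high
  expect_gt(rep$stats_residual$pearson_r, 0.8)
})

test_that("PCA of causal-flow vectors separates constructed blocks", {
  ids <- paste0("u", 1:10)
  vals <- matrix(0.05, 10, 10)
  vals[1:5, 1:5] <- 1; vals[6:10, 6:10] <- 1 # two orthogonal blocks
  m <- new_conn_matrix(vals, "ccm", ids, subclass = "cf_matrix",
                       labels = rep(c("A", "B"), each = 5))
  sc <- cf_hierarchy_pca(m, seed = 1)
  expect_equal(length(unique(sc$cluster[1:5])), 1)
  expect_equal(length(unique(sc$cluster[6:10])), 1)
  expect_false(sc$cluster[1] == sc$cluster[6])
  expect_gt(attr(sc, "silhouette"), 0.5)
  # identical columns: no structure, silhouette flagged ~0
  m0 <- new_conn_matrix(matrix(1, 10, 10), "ccm", ids, subclass = "cf_matrix")
  sc0 <- cf_hierarchy_pca(m0)
  expect_lt(abs(attr(sc0, "silhouette")), 0.1)
  expect_error(cf_hierarchy_pca(new_conn_matrix(matrix(1, 2, 2), "m",
                                                c("a", "b"))), "3 units")
})

test_that("subnetwork identity is recoverable from simulated causal flow", {
  skip_if_not_installed("mclust")
  sim <- simulate_network(sim_params(seed = 1))
  sub <- subset_units(decimate_ensemble(sim, 10),
                      c("x1", "x2", "x3",
                        paste0("y", c(4, 20, 36, 52, 68, 84, 100))))
  cf <- compute_cf_matrix(sub, d = 5, tau = 4)
  sc <- cf_hierarchy_pca(cf, seed = 1)
  ari <- mclust::adjustedRandIndex(sc$cluster, sub$labels)
  expect_equal(ari, 1)
})
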