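grid_200 <- build_lookup_grid(resolution = 200)

test_that("lookup grid nodes equal direct forward-model evaluation", {
  tab <- hg_collection_table()
  g <- grid_200
  expect_equal(g$mu_pred[which.min(abs(g$mus_axis - 10)), 1],
               forward_attenuation(
                 optical_properties(0.01, g$mus_axis[which.min(abs(g$mus_axis - 10))], 0),
                 tab))
  ## spot-check a random set of nodes against scalar evaluation
  set.seed(3)
  for (k in 1:10) {
    i <- sample(length(g$mus_axis), 1); j <- sample(length(g$g_axis), 1)
    p <- optical_properties(0.01, g$mus_axis[i], g$g_axis[j])
    expect_equal(g$mu_pred[i, j], forward_attenuation(p, tab))
    expect_equal(g$rho_pred[i, j], forward_reflectivity(p, g$l_cg, tab))
  }
  ## rho decreases with g at fixed mu_s
  expect_true(all(diff(g$rho_pred[100, ]) <= 1e-15))
})

test_that("inversion round trip recovers (mu_s, g) to grid resolution", {
  g <- grid_200
  tab <- hg_collection_table()
  p <- optical_properties(0.01, 40, 0.87)
  iv <- invert_properties(forward_attenuation(p, tab),
                          forward_reflectivity(p, g$l_cg, tab), g)
  expect_equal(iv$mu_s, 40, tolerance = diff(g$mus_axis)[1] / 40)
  expect_equal(iv$g, 0.87, tolerance = diff(g$g_axis)[1])
  expect_identical(iv$flag, "ok")
  expect_error(invert_properties(5, 0, g), "rho_obs")
  expect_error(invert_properties(0.005, 1e-6, g), "mu_obs")
})

test_that("round-trip errors stay within twice the grid spacing over the envelope", {
  g <- grid_200
  tab <- hg_collection_table()
  set.seed(7)
  n <- 200
  mus <- runif(n, 1, 75)
  gs <- runif(n, 0, 0.97)
  dg <- diff(g$g_axis)[1]; dm <- diff(g$mus_axis)[1]
  for (k in seq_len(n)) {
    p <- optical_properties(0.01, mus[k], gs[k])
    iv <- invert_properties(forward_attenuation(p, tab),
                            forward_reflectivity(p, g$l_cg, tab), g)
    expect_lte(abs(iv$g - gs[k]), 2 * dg)
    expect_lte(abs(iv$mu_s - mus[k]) / mus[k], 2 * dm / mus[k])
  }
})

test_that("at fixed attenuation, higher reflectivity maps to lower anisotropy", {
  g <- grid_200
  rhos <- 10^seq(-7, -5, length.out = 9)
  ginv <- sapply(rhos, function(r) invert_properties(8, r, g)$g)
  expect_true(all(diff(ginv) <= 1e-9))
})

test_that("per-sample aggregation uses outlier-robust medians", {
  fits <- data.frame(sample_id = "s1", feature = "septa", layer = "superficial",
                     mu_s = c(1, 2, 100), g = c(0.5, 0.6, 0.99))
  agg <- aggregate_by_feature(fits)
  expect_equal(agg$mu_s, 2)
  expect_equal(agg$n, 3)
  one <- aggregate_by_feature(data.frame(sample_id = "s", feature = "spines",
                                         layer = "volumetric", mu_s = 7, g = 0.1))
  expect_equal(one$mu_s, 7)
  ## brute-force sort-based median oracle on random tables
  set.seed(9)
  tab <- data.frame(sample_id = sample(c("a", "b"), 60, TRUE),
                    feature = sample(c("columella", "grooves"), 60, TRUE),
                    layer = "superficial",
                    mu_s = rexp(60, 0.1), g = runif(60))
  agg <- aggregate_by_feature(tab)
  for (r in seq_len(nrow(agg))) {
    sub <- tab[tab$sample_id == agg$sample_id[r] & tab$feature == agg$feature[r], ]
    v <- sort(sub$mu_s)
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(agg$mu_s[r], med)
  }
})

test_that("percent difference reproduces the depth-contrast convention", {
  expect_equal(percent_difference(52.92, 39.56), 33.77, tolerance = 1e-3)
  expect_equal(percent_difference(0.87, 0.83), 4.819, tolerance = 1e-3)
  expect_error(percent_difference(1, 0), "non-zero")
})
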