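make_phi_model <- function(phi_vals, labels, pitch = 0.1) {
  d <- dim(labels)
  model <- voxel_model(labels, pitch)
  fl <- structure(list(phi = array(phi_vals, dim = d)), class = "fluence_volume")
  list(fl = fl, model = model)
}

test_that("layer summaries of a constant field are degenerate as expected", {
  lab <- array(2L, dim = c(4, 4, 4))
  x <- make_phi_model(rep(1, 64), lab)
  s <- summarize_layer(x$fl, x$model, 2)
  expect_equal(s$mean, 1); expect_equal(s$median, 1); expect_equal(s$p95, 1)
  expect_equal(s$variance, 0); expect_equal(s$range, 0)
  expect_error(summarize_layer(x$fl, x$model, 1), "not present")
})

test_that("p95 agrees with a sort-based quantile oracle", {
  lab <- array(3L, dim = c(5, 5, 4))
  vals <- as.numeric(1:100)
  x <- make_phi_model(vals, lab)
  s <- summarize_layer(x$fl, x$model, 3)
  ## type-7: 1 + 0.95 * 99 = 95.05 -> linear interpolation
  v <- sort(vals)
  h <- 1 + 0.95 * (length(v) - 1)
  oracle <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  expect_equal(s$p95, oracle)
  expect_gte(s$p95, s$median)
})

test_that("moments of a lognormal layer match closed forms", {
  set.seed(31)
  lab <- array(2L, dim = c(50, 50, 40))
  vals <- stats::rlnorm(50 * 50 * 40, 0, 0.5)
  x <- make_phi_model(vals, lab)
  s <- summarize_layer(x$fl, x$model, 2)
  expect_equal(s$mean, exp(0.125), tolerance = 0.02)
  expect_equal(s$median, 1, tolerance = 0.02)
  expect_equal(s$variance, (exp(0.25) - 1) * exp(0.25), tolerance = 0.05)
  sk <- (exp(0.25) + 2) * sqrt(exp(0.25) - 1)
  expect_equal(s$skewness, sk, tolerance = 0.1)
  expect_equal(s$kurtosis_excess, s$kurtosis - 3)
})

test_that("summaries are invariant to voxel ordering", {
  lab <- array(3L, dim = c(4, 4, 4))
  set.seed(8)
  vals <- stats::rexp(64)
  s1 <- summarize_layer(make_phi_model(vals, lab)$fl,
                        make_phi_model(vals, lab)$model, 3)
  perm <- sample(64)
  s2 <- summarize_layer(make_phi_model(vals[perm], lab)$fl,
                        make_phi_model(vals, lab)$model, 3)
  for (f in c("mean", "median", "variance", "p95", "range", "skewness"))
    expect_equal(s2[[f]], s1[[f]])
})

test_that("interface enhancement takes p95 over skeleton voxels touching water", {
  lab <- array(0L, dim = c(5, 5, 5))
  lab[, , 1:2] <- 1L
  lab[, , 3:5] <- 3L
  phi <- array(0.5, dim = c(5, 5, 5))
  ## uniform field: enhancement is exactly the field value
  x <- make_phi_model(phi, lab)
  expect_equal(interface_enhancement(x$fl, x$model), 0.5)
  ## hand-built interface values: the 25 voxels of slab z = 3 touch water
  vals <- phi
  iface_vals <- seq(1, 3, length.out = 25)
  vals[, , 3] <- matrix(iface_vals, 5, 5)
  x2 <- make_phi_model(vals, lab)
  v <- sort(iface_vals)
  h <- 1 + 0.95 * 24
  oracle <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  expect_equal(interface_enhancement(x2$fl, x2$model), oracle)
  expect_error(interface_enhancement(x2$fl,
                                     voxel_model(array(3L, dim = c(5, 5, 5)), 0.1)),
               "water")
})

test_that("layer statistics are self-consistent with the deposition tally", {
  m <- slab_model(12, 12, 12, 0.1, optical_properties(0.05, 5, 0.5))
  fl <- run_simulation(m, simulation_config(n_photons = 2e4, seed = 13))
  s <- summarize_layer(fl, m, 3)
  ## mean(phi) * mu_a * voxel volume * n_voxels * irradiance = deposited energy
  irr <- fl$n_photons / (12 * 12 * 0.1^2)
  lhs <- s$mean * 0.05 * 0.1^3 * s$n_voxels * irr
  expect_equal(lhs, sum(fl$deposited[m$labels == 3L]), tolerance = 1e-6)
})
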