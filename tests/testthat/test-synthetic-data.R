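test_that("noise-free A-scans are an exact forward-inverse pair with the fitter", {
  sp <- ascan_spec(speckle = FALSE)
  sim <- simulate_ascan_profile(sp)
  pr <- sim$profile
  expect_identical(pr$surface_index, sp$surface_index)
  f1 <- fit_layer(pr, 0, sp$d1_mm)
  f2 <- fit_layer(pr, sp$d1_mm, max(pr$depth_mm))
  expect_equal(f1$rho, sp$rho1, tolerance = 1e-6)
  expect_equal(f1$mu, sp$mu1, tolerance = 1e-6)
  expect_equal(f2$mu, sp$mu2, tolerance = 1e-6)
  expect_equal(correct_deep_layer(f2$rho, sp$mu1, sp$d1_mm, sp$r_sp),
               sp$rho2, tolerance = 1e-6)
})

test_that("A-scan generation is deterministic under seed", {
  s1 <- simulate_ascan(ascan_spec(), seed = 99)
  s2 <- simulate_ascan(ascan_spec(), seed = 99)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_ascan(ascan_spec(), seed = 100)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("full pipeline recovers two-layer truth from speckled ensembles", {
  set.seed(77)
  sp <- ascan_spec(speckle = TRUE)
  fits <- t(replicate(150, {
    sim <- simulate_ascan_profile(sp)
    f <- fit_ascan(sim$profile, r_sp = sp$r_sp)
    c(f$rho_superficial, f$mu_superficial, f$rho_volumetric, f$mu_volumetric)
  }))
  truth <- c(sp$rho1, sp$mu1, sp$rho2, sp$mu2)
  med <- apply(fits, 2, median)
  expect_true(all(abs(med / truth - 1) <= 0.10))
})

test_that("phantom series spans the standard concentration range with linear mu", {
  ph <- make_phantom_series(speckle = FALSE)
  expect_equal(nrow(ph$theory), 5)
  expect_equal(min(ph$theory$concentration), 2.84e12)
  expect_equal(max(ph$theory$concentration), 4.55e13)
  ## attenuation linear in concentration through the origin (mu_a offset)
  pred <- 0.01 + (ph$theory$mu[1] - 0.01) * ph$theory$concentration / ph$theory$concentration[1]
  expect_equal(ph$theory$mu, pred, tolerance = 1e-9)
  ## pipeline recovery of mu from the noise-free scans
  mu_fit <- sapply(ph$scans, function(s)
    fit_layer(s$profile, 0, 0.55)$mu)
  expect_equal(mu_fit, ph$theory$mu, tolerance = 0.01)
})

test_that("phantom scattering recovery is unbiased at each concentration", {
  set.seed(55)
  tab <- hg_collection_table()
  ph0 <- make_phantom_series(speckle = FALSE)
  for (i in c(3, 5)) {
    conc <- ph0$theory$concentration[i]
    mus_hat <- replicate(100, {
      ph <- make_phantom_series(concentrations = conc, speckle = TRUE)
      f <- fit_layer(ph$scans[[1]]$profile, 0, 0.55)
      ## invert attenuation at the known Mie anisotropy
      a_g <- collection_factors(ph$theory$g[1], tab)$a_g
      (f$mu - 0.01) / a_g
    })
    expect_equal(median(mus_hat), ph0$theory$mu_s[i], tolerance = 0.1)
  }
})

test_that("coral geometry generator is deterministic, watertight and contrastive", {
  s1 <- make_coral_geometry(coral_geometry_spec("shallow", seed = 5))
  s2 <- make_coral_geometry(coral_geometry_spec("shallow", seed = 5))
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$faces, s2$faces)
  expect_true(is_watertight(s1))
  ## flat plate degenerates to rugosity 1
  flat <- make_coral_geometry(coral_geometry_spec(
    "shallow", cup_depth_mm = 1e-9, spine_density_mm2 = 0, groove_depth_mm = 0,
    septa_amp_mm = 0, seed = 1))
  expect_equal(rugosity_index(flat), 1, tolerance = 1e-6)
  ## shallow corallites rougher than mesophotic ones across seeds
  wins <- sapply(1:5, function(sd) {
    sh <- make_coral_geometry(coral_geometry_spec("shallow", seed = sd))
    me <- make_coral_geometry(coral_geometry_spec("mesophotic", seed = sd))
    spc_s <- coral_geometry_spec("shallow", seed = sd)
    spc_m <- coral_geometry_spec("mesophotic", seed = sd)
    win <- function(spc) {
      c0 <- spc$cup_spacing_mm / 2
      list(x = c(c0 - 1, c0 + 1), y = c(c0 - 1, c0 + 1))
    }
    rugosity_index(sh, win(spc_s)) > rugosity_index(me, win(spc_m))
  })
  expect_true(all(wins))
  expect_error(coral_geometry_spec("shallow", cup_spacing_mm = 1.5), "overlap")
})
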