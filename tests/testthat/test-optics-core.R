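test_that("Fresnel normal-incidence reflectance matches the closed form", {
  expect_identical(fresnel_specular_reflectance(1.33, 1.33), 0)
  expect_equal(fresnel_specular_reflectance(1.00, 1.52), ((0.52) / 2.52)^2)
  expect_equal(fresnel_specular_reflectance(1.00, 1.52), 0.04256, tolerance = 1e-3)
  expect_equal(fresnel_specular_reflectance(1.33, 1.52), 0.00444, tolerance = 1e-2)
  ## symmetry and monotonicity in the index contrast at fixed sum
  expect_equal(fresnel_specular_reflectance(1.2, 1.5),
               fresnel_specular_reflectance(1.5, 1.2))
  r <- sapply(seq(0, 0.4, by = 0.05),
              function(d) fresnel_specular_reflectance(1.4 - d / 2, 1.4 + d / 2))
  expect_true(all(diff(r) > 0))
  expect_error(fresnel_specular_reflectance(-1, 1.5), "indices")
})

test_that("Mie phantom properties agree with an independent Mie-series oracle", {
  ## frozen values from a scipy.special direct Riccati-Bessel implementation
  ## (100 nm polystyrene, n = 1.59, in water at 930 nm)
  mp <- mie_phantom_properties(100, 1.59, 1.33, 930, 4.55e13)
  expect_equal(mp$mu_s, 0.582934654, tolerance = 1e-3)
  expect_equal(mp$g, 0.03487108, tolerance = 1e-3)
  expect_equal(mp$csca_nm2, 12.8117506, tolerance = 1e-3)
  ## 100 nm spheres at 930 nm are near-Rayleigh: weak anisotropy
  expect_lt(mp$g, 0.1)
})

test_that("Mie scattering coefficient is exactly linear in concentration", {
  c0 <- 3.7e12
  m1 <- mie_phantom_properties(100, 1.59, 1.33, 930, c0)
  m2 <- mie_phantom_properties(100, 1.59, 1.33, 930, 2 * c0)
  expect_equal(m2$mu_s, 2 * m1$mu_s)
  expect_identical(mie_phantom_properties(100, 1.59, 1.33, 930, 0)$mu_s, 0)
  expect_error(mie_phantom_properties(100, 1.59, 1.33, -5, 1e12), "wavelength")
  expect_error(mie_phantom_properties(-1, 1.59, 1.33, 930, 1e12), "diameter")
})

test_that("collection-factor table honours its endpoint anchors and shape", {
  tab <- hg_collection_table()
  cf0 <- collection_factors(0, tab)
  expect_equal(cf0$a_g, 1.0)
  expect_equal(cf0$b_g, 1.04e-4)
  cf1 <- collection_factors(1, tab)
  expect_equal(cf1$a_g, 0)
  expect_equal(cf1$b_g, 0)
  ## monotone non-increasing over the grid
  expect_true(all(diff(tab$a_g) <= 1e-12))
  expect_true(all(diff(tab$b_g) <= 1e-12))
  ## interpolation reproduces table nodes exactly
  nodes <- tab$g[c(5, 101, 500, 900)]
  cf <- collection_factors(nodes, tab)
  expect_equal(cf$a_g, tab$a_g[c(5, 101, 500, 900)])
  expect_equal(cf$b_g, tab$b_g[c(5, 101, 500, 900)])
  expect_error(collection_factors(1.2, tab), "g must")
})

test_that("collection-factor tables round trip through CSV", {
  tab <- hg_collection_table(n_grid = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_collection_table(tab, path)
  tab2 <- read_collection_table(path)
  expect_equal(tab2$a_g, tab$a_g)
  expect_equal(tab2$b_g, tab$b_g)
})

test_that("forward attenuation follows mu = (a(g) mu_s + mu_a) G(NA)", {
  tab <- hg_collection_table()
  expect_equal(forward_attenuation(optical_properties(0.01, 10, 0), tab), 10.01)
  expect_equal(forward_attenuation(optical_properties(0.01, 0, 0.7), tab), 0.01)
  a09 <- collection_factors(0.9, tab)$a_g
  expect_equal(forward_attenuation(optical_properties(0.01, 10, 0.9), tab),
               10 * a09 + 0.01)
  ## monotone in mu_s at fixed g
  mus <- seq(1, 60, by = 5)
  mu <- sapply(mus, function(m)
    forward_attenuation(optical_properties(0.01, m, 0.5), tab))
  expect_true(all(diff(mu) > 0))
})

test_that("forward reflectivity follows rho = mu_s L_cg b(g, NA)", {
  tab <- hg_collection_table()
  expect_equal(forward_reflectivity(optical_properties(0.01, 0, 0.3), 0.0041, tab), 0)
  expect_equal(forward_reflectivity(optical_properties(0.01, 50, 0), 0.0041, tab),
               50 * 0.0041 * 1.04e-4)
  expect_equal(forward_reflectivity(optical_properties(0.01, 30, 1 - 1e-9), 0.0041,
                                    tab), 0, tolerance = 1e-10)
  rho <- sapply(seq(1, 60, by = 5), function(m)
    forward_reflectivity(optical_properties(0.01, m, 0.5), 0.0041, tab))
  expect_true(all(diff(rho) > 0))
  expect_error(forward_reflectivity(optical_properties(0.01, 10, 0), -1, tab),
               "coherence-gate")
})

test_that("optical property and instrument constructors enforce invariants", {
  expect_error(optical_properties(g = 1), "g must")
  expect_error(optical_properties(mu_s = -1), "mu_s")
  expect_error(instrument_constants(na = 1.2), "aperture")
  inst <- instrument_constants()
  expect_equal(inst$pitch_mm, 2 / 681)
})
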