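test_that("signal calibration recovers (a, b) and is robust to count noise", {
  r <- c(0.04, 0.004, 0.0006)
  counts <- 80 + 10 * log(r)
  cal <- fit_signal_calibration(r, counts)
  expect_equal(cal$intercept_a, 80, tolerance = 1e-12)
  expect_equal(cal$slope_b, 10, tolerance = 1e-12)
  ## the three standard glass reference interfaces with 1% count noise
  r3 <- fresnel_specular_reflectance(1.52, c(1.00, 1.33, 1.46))
  set.seed(1)
  slopes <- replicate(50, {
    cts <- 80 + 10 * log(r3)
    cts <- cts * (1 + stats::rnorm(3, sd = 0.01))
    fit_signal_calibration(r3, cts)$slope_b
  })
  expect_lt(abs(median(slopes) - 10) / 10, 0.01 * 3)
  expect_error(fit_signal_calibration(c(0.1, 0.1), c(5, 6)), "distinct")
  expect_error(fit_signal_calibration(c(0.1, -0.2), c(5, 6)), "> 0")
})

test_that("counts-to-reflectance inverts the log encoding exactly", {
  cal <- list(intercept_a = 80, slope_b = 10)
  expect_equal(counts_to_reflectance(80, cal), 1.0)
  expect_equal(counts_to_reflectance(80 + 10 * log(0.01), cal), 0.01)
  cts <- c(12, 50, 80, 95.5)
  expect_equal(reflectance_to_counts(counts_to_reflectance(cts, cal), cal), cts)
  expect_true(all(diff(counts_to_reflectance(cts, cal)) > 0))
})

test_that("surface detection picks the reflectance maximum, shallow-first", {
  x <- rep(0.1, 300); x[137] <- 5
  expect_identical(detect_surface(x), 137L)
  y <- rep(0.1, 100); y[c(50, 90)] <- 2
  expect_identical(detect_surface(y), 50L)
  expect_error(detect_surface(rep(1, 10)), "flat")
  expect_error(detect_surface(numeric(0)), "empty")
})

test_that("layer fitting recovers an exact exponential to machine precision", {
  pitch <- 2 / 681
  z <- (0:600) * pitch
  r <- 0.01 * exp(-2 * 5 * z)
  r[1] <- 0.05  # surface peak at index 1
  pr <- ascan_profile(z, r, surface_index = 1, noise_floor = 0)
  f <- fit_layer(pr, 0, max(z))
  expect_equal(f$rho, 0.01, tolerance = 1e-9)
  expect_equal(f$mu, 5.0, tolerance = 1e-9)
  expect_gte(f$r2, 0.999)
  expect_error(fit_layer(pr, 0, 8 * pitch, min_points = 5), "too few")
})

test_that("two-layer segmentation finds the breakpoint and flags single layers", {
  pitch <- 2 / 681
  z <- (0:680) * pitch
  ## continuous two-slope log profile breaking 0.10 mm below the surface
  z0 <- z[40]
  lnr <- ifelse(z - z0 <= 0.1, log(4e-4) - 2 * 40 * (z - z0),
                log(4e-4) - 2 * 40 * 0.1 - 2 * 3 * (z - z0 - 0.1))
  r <- exp(lnr); r[z <= z0] <- 1e-10; r[40] <- 0.02
  pr <- ascan_profile(z, r, surface_index = 40, noise_floor = 1e-9)
  seg <- segment_two_layers(pr)
  expect_false(seg$single_layer)
  expect_lt(abs(seg$transition_depth_mm - 0.1), pitch + 1e-12)
  ## single slope: flagged
  r1 <- exp(log(4e-4) - 2 * 10 * (z - z0)); r1[z <= z0] <- 1e-10; r1[40] <- 0.02
  pr1 <- ascan_profile(z, r1, surface_index = 40, noise_floor = 1e-9)
  expect_true(segment_two_layers(pr1)$single_layer)
})

test_that("breakpoint is stable under multiplicative speckle noise", {
  pitch <- 2 / 681
  set.seed(101)
  errs <- replicate(120, {
    sim <- simulate_ascan_profile(ascan_spec(speckle = TRUE))
    seg <- segment_two_layers(sim$profile)
    seg$transition_depth_mm - 0.1
  })
  expect_lte(median(abs(errs)) / pitch, 2)
})

test_that("deep-layer correction inverts interface and overburden losses", {
  expect_equal(correct_deep_layer(3e-6, 0, 0.1, 0), 3e-6)
  expect_equal(correct_deep_layer(1e-6, 40, 0.1, 0.02),
               1e-6 / (0.98^2 * exp(-8)))
  expect_gte(correct_deep_layer(1e-6, 5, 0.2, 0.1), 1e-6)
  expect_error(correct_deep_layer(1e-6, 40, 0.1, 1), "specular")
  expect_error(correct_deep_layer(1e-6, 40, -1, 0.5), "thickness")
  ## forward-inverse consistency through the generator (noise off)
  sp <- ascan_spec(speckle = FALSE)
  sim <- simulate_ascan_profile(sp)
  f <- fit_ascan(sim$profile, r_sp = sp$r_sp)
  expect_equal(f$rho_volumetric, sp$rho2, tolerance = 0.05)
})

test_that("attenuation estimates are invariant to count offsets when recalibrated", {
  sp <- ascan_spec(speckle = FALSE)
  sim <- simulate_ascan(sp)
  cal1 <- sp$calibration
  ## shift all counts by a constant; refit calibration with the same shift
  cal2 <- list(intercept_a = cal1$intercept_a + 37, slope_b = cal1$slope_b)
  p1 <- ascan_profile(sim$depth_mm, counts_to_reflectance(sim$counts, cal1))
  p2 <- ascan_profile(sim$depth_mm,
                      counts_to_reflectance(sim$counts + 37, cal2))
  f1 <- fit_ascan(p1, r_sp = sp$r_sp)
  f2 <- fit_ascan(p2, r_sp = sp$r_sp)
  expect_equal(f2$mu_superficial, f1$mu_superficial, tolerance = 1e-10)
  expect_equal(f2$mu_volumetric, f1$mu_volumetric, tolerance = 1e-10)
})
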