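#!/usr/bin/env Rscript
# A-scan fitting stage: recovery of two-layer optical structure from
# synthetic speckled OCT depth profiles.
#
# Each profile carries a specular surface peak, a highly scattering ~100 um
# superficial layer (mu1 = 40 /mm) and a more transmissive volumetric layer
# (mu2 = 3 /mm). The pipeline detects the surface, locates the slope
# transition with a continuous two-segment fit, fits R(z) = rho exp(-2 mu z)
# per layer (excluding the five pixels after the peak), and corrects the
# deep-layer reflectivity for interface and overburden losses.
#
# Findings with the default seed: ensemble-median estimates of rho and mu
# land within a few percent of truth for both layers and the transition is
# located to a fraction of a pixel in the median.

library(coraloptics)
dir.create("results", showWarnings = FALSE)
set.seed(201)

sp <- ascan_spec(speckle = TRUE)
fits <- t(replicate(200, {
  sim <- simulate_ascan_profile(sp)
  f <- fit_ascan(sim$profile, r_sp = sp$r_sp)
  c(rho_sup = f$rho_superficial, mu_sup = f$mu_superficial,
    rho_vol = f$rho_volumetric, mu_vol = f$mu_volumetric,
    d1 = f$transition_depth_mm)
}))
truth <- c(sp$rho1, sp$mu1, sp$rho2, sp$mu2, sp$d1_mm)
summary_tab <- data.frame(
  parameter = c("rho_superficial", "mu_superficial", "rho_volumetric",
                "mu_volumetric", "transition_depth_mm"),
  truth = truth,
  median_estimate = apply(fits, 2, median),
  median_rel_err_pct = 100 * (apply(fits, 2, median) / truth - 1),
  mad_rel_err_pct = 100 * apply(abs(sweep(fits, 2, truth, "/") - 1), 2, median))
print(summary_tab, digits = 3)
write.csv(summary_tab, "results/02_ascan_recovery.csv", row.names = FALSE)
cat(sprintf("breakpoint located within %.2f px of 100 um in the median\n",
            median(abs(fits[, 5] - sp$d1_mm)) / sp$pitch_mm))
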