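#!/usr/bin/env Rscript
# Inversion stage: from observed (mu, rho) to inherent (mu_s, g) on the
# lookup grid, and the worked depth contrasts from the reference medians.
#
# The forward model mu = (a(g) mu_s + mu_a) G(NA), rho = mu_s L_cg b(g, NA)
# is tabulated on a 200 x 200 grid and inverted by nearest prediction in
# (ln mu, ln rho) with iterative local bilinear refinement.
#
# Findings with the default seed: the round trip over 1000 random property
# pairs is exact to well under the grid spacing, and the reference feature
# medians reproduce the printed depth contrasts (grooves' superficial mu_s
# ~34% higher in mesophotic colonies; spines' superficial g ~5% higher in
# shallow ones).

library(coraloptics)
dir.create("results", showWarnings = FALSE)
set.seed(301)

grid <- build_lookup_grid(resolution = 200)
tab <- hg_collection_table()
n <- 1000
draws <- data.frame(mu_s = runif(n, 1, 75), g = runif(n, 0, 0.97))
inv <- t(apply(draws, 1, function(r) {
  p <- optical_properties(0.01, r[1], r[2])
  iv <- invert_properties(forward_attenuation(p, tab),
                          forward_reflectivity(p, grid$l_cg, tab), grid)
  c(iv$mu_s, iv$g, iv$residual)
}))
cat(sprintf("round trip: max |g err| = %.2e, max rel mu_s err = %.2e\n",
            max(abs(inv[, 2] - draws$g)),
            max(abs(inv[, 1] - draws$mu_s) / draws$mu_s)))
write.csv(cbind(draws, mu_s_inv = inv[, 1], g_inv = inv[, 2], residual = inv[, 3]),
          "results/03_inversion_roundtrip.csv", row.names = FALSE)

## worked depth contrasts from the reference medians --------------------------
ref <- reference_feature_medians()
pick <- function(f, l, d, m)
  ref$value[ref$feature == f & ref$layer == l & ref$depth_zone == d & ref$metric == m]
contrasts <- data.frame(
  contrast = c("grooves superficial mu_s, mesophotic vs shallow",
               "spines superficial g, shallow vs mesophotic"),
  percent = c(
    percent_difference(pick("grooves", "superficial", "mesophotic", "mu_s"),
                       pick("grooves", "superficial", "shallow", "mu_s")),
    percent_difference(pick("spines", "superficial", "shallow", "g"),
                       pick("spines", "superficial", "mesophotic", "g"))))
print(contrasts, digits = 3)
write.csv(contrasts, "results/03_depth_contrasts.csv", row.names = FALSE)
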