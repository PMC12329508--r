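# coraloptics

Bio-optical analysis of coral skeletons: depth-resolved inherent optical
properties from OCT reflectance profiles, layered voxel models from 3-D
skeletal meshes, voxel Monte Carlo simulation of light fluence, and the
downstream rugosity, fluence-distribution and group statistics.

## The problem

Coral skeletons are dense aragonite scatterers that redistribute light for
the coral's photosymbiotic algae — a function that matters most on mesophotic
reefs (below ~30 m), where light is scarce. Quantifying that redistribution
needs three linked computations, which this package provides for
ecophysiologists and tissue-optics researchers:

1. **From OCT signal to layer optics.** A calibrated A-scan follows
   `R(z) = ρ e^(−2μz)`; the skeleton resolves into a highly scattering
   ~100 µm superficial layer and a more transmissive volumetric layer, each
   with a local reflectivity ρ and one-way attenuation μ (= −slope/2, mm⁻¹).
2. **From (μ, ρ) to (μs, g).** The forward model
   `μ = (a(g)·μs + μa)·G(NA)` and `ρ = μs·L_cg·b(g, NA)` links observables to
   the scattering coefficient μs and scattering anisotropy g; the package
   tabulates it on a lookup grid and inverts measured pairs.
3. **From structure to light fields.** Triangulated skeletal surfaces are
   voxelized (300 px/cm), split into superficial shell / volumetric interior,
   topped with a 100-voxel water column, and traversed by a Monte Carlo
   photon transport engine (930 nm, collimated, Henyey–Greenstein phase
   function) that scores the fluence rate Φ normalised to the incident
   irradiance (Φ = 1).

A synthetic-data module generates speckled two-layer A-scans, Mie-calibrated
nanoparticle phantom series, and watertight coral-like plate geometries
(shallow / mesophotic presets), so the full pipeline runs and is tested
without any instrument data.

## Worked example

```r
library(coraloptics)

# simulate a speckled two-layer skeletal A-scan and fit it
sp  <- ascan_spec(speckle = TRUE)        # mu1 = 40, mu2 = 3 /mm, 100 um layer
sim <- simulate_ascan_profile(sp, seed = 7)
fit <- fit_ascan(sim$profile, r_sp = sp$r_sp)
str(fit[c("rho_superficial", "mu_superficial", "mu_volumetric",
          "transition_depth_mm")])
#> List of 4
#>  $ rho_superficial    : num 1.26e-06
#>  $ mu_superficial     : num 39.7
#>  $ mu_volumetric      : num 2.98
#>  $ transition_depth_mm: num 0.103

# invert the superficial-layer fit into inherent properties
grid <- build_lookup_grid(resolution = 200)
inv  <- invert_properties(fit$mu_superficial, fit$rho_superficial, grid)
cat(sprintf("mu_s = %.1f /mm, g = %.3f (flag: %s)\n", inv$mu_s, inv$g, inv$flag))
#> mu_s = 41.5 /mm, g = 0.776 (flag: ok)

# a mesophotic-style plate under collimated 930 nm light
mesh <- make_coral_geometry(coral_geometry_spec("mesophotic", plate_mm = 6, seed = 2))
vm <- add_water_layer(split_layers(voxelize_mesh(mesh, 150), 0.1), 100)
vm <- assign_properties(vm,
  superficial = optical_properties(0.01, 52.92, 0.83),
  volumetric  = optical_properties(0.01, 3.2, 0.70))
fl <- run_simulation(vm, simulation_config(n_photons = 1e6, seed = 3))
cat(sprintf("interface fluence p95 = %.2f x incident\n",
            interface_enhancement(fl, vm)))
#> interface fluence p95 = 2.17 x incident
```

Reading: the fitted A-scan recovers the generating attenuations (39.7 and
2.98 mm⁻¹ against 40 and 3) and locates the layer transition at 103 µm; the
inversion places the superficial layer at μs ≈ 41 mm⁻¹ with strongly
forward-directed scattering (g ≈ 0.78); and in the simulated light field the
skeleton–water interface sees up to ~2.2× the incident light (95th
percentile) — backscatter build-up concentrating light right where the
tissue would sit.

## Analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end and write
tables under `results/`:

| script | stage |
|---|---|
| `01_calibration_phantoms.R` | Fresnel reference calibration + Mie phantom series |
| `02_ascan_recovery.R` | two-layer recovery study on speckled A-scans |
| `03_inversion_map.R` | lookup-grid round trip + worked depth contrasts |
| `04_geometry_rugosity.R` | preset geometries, voxel bookkeeping, rugosity |
| `05_light_simulation.R` | Monte Carlo fluence fields and layer statistics |
| `06_group_comparisons.R` | Hedges' g, bootstrap CIs, blocked permutation test |

The methods vignette (`vignettes/coral-skeleton-optics.Rmd`) documents the
models, parameter defaults, numerical choices and limitations.

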