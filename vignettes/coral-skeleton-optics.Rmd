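---
title: "Coral skeleton bio-optics: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coral skeleton bio-optics: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coraloptics)
```

## What this package computes

Coral skeletons are strongly scattering aragonite matrices whose
microstructure redistributes the light reaching the coral's photosymbionts.
`coraloptics` implements the full chain from optical coherence tomography
(OCT) depth profiles to simulated light fields:

1. **Signal calibration** — raw OCT counts are log-encoded,
   $OCT(z) = a + b\,\ln R(z)$; $(a, b)$ is fit from reference interfaces of
   known Fresnel reflectance and validated against a Mie-calibrated
   nanoparticle phantom series.
2. **Two-layer A-scan fitting** — each depth profile
   $R(z) = \rho\, e^{-2\mu z}$ is segmented into a highly scattering
   superficial layer (~100 µm) and a more transmissive volumetric layer, with
   per-layer local reflectivity $\rho$ and one-way attenuation
   $\mu = -\mathrm{slope}/2$.
3. **Inversion** — observed $(\mu, \rho)$ are mapped to the inherent
   scattering coefficient $\mu_s$ and anisotropy $g$ through the forward model
   $\mu = (a(g)\mu_s + \mu_a)\,G(NA)$, $\rho = \mu_s L_{cg}\, b(g, NA)$ on a
   lookup grid.
4. **Geometry** — triangulated skeletal surfaces are voxelized (300 px/cm),
   split into the 100 µm superficial shell and volumetric interior by exact
   Euclidean distance transform, and overlaid with a 100-voxel water column.
5. **Photon transport** — a voxel Monte Carlo engine (hop/drop/spin with
   Henyey–Greenstein scattering, in the mcxyz tradition) scores the
   incident-normalised fluence rate $\Phi$ from absorbed energy.
6. **Statistics** — per-layer fluence distributions, the skeleton–water
   interface enhancement (p95 of $\Phi$ over interface voxels), rugosity,
   and depth contrasts via Hedges' $g$ with bootstrap CIs and a
   colony-blocked permutation test.

Everything runs on synthetic data generated by the package itself, so the
pipeline is fully testable without instrument access.

## The collection factors a(g) and b(g, NA)

The inversion needs two instrument-specific scalar factors. $a(g)$ is the
fraction of scattering events that remove light from the detection acceptance;
it falls from 1 at $g = 0$ to 0 at $g = 1$, which is why strongly
forward-scattering media attenuate the detected signal less per unit $\mu_s$.
$b(g, NA)$ is the fraction of coherence-gated scattered light that returns
into the collection cone; for NA = 0.075 it falls from $1.04\times10^{-4}$ at
$g = 0$ to 0 at $g = 1$.

No closed form for either factor is published for this instrument class, only
the endpoint behaviour above. The package therefore derives a default table
from the Henyey–Greenstein phase function: $a(g)$ as the HG probability of
deflection beyond the acceptance half-angle $\arcsin(NA)$ and $b(g, NA)$ as
the HG probability of deflection into the backward cone of the same
half-angle, each rescaled linearly so the endpoint anchors hold exactly. The
HG cumulative distribution has a closed form, so the integrals are evaluated
analytically rather than by quadrature. The table is a plain CSV
(`g,a_g,b_g`) and fully user-replaceable via `read_collection_table()`, so an
exact instrument model can be substituted without touching the inversion.

## Inversion metric and refinement

$\rho$ spans several orders of magnitude (bounded above by
$\mu_s L_{cg} \cdot 1.04\times10^{-4}$), so the inverter minimises squared
distance in $(\ln\mu, \ln\rho)$. The anisotropy axis is capped at 0.99: as
$g \to 1$, $b \to 0$ and the observation loses all sensitivity to $g$, so
observations mapping beyond the envelope are flagged `non_invertible` rather
than extrapolated. After the nearest grid node is found, the minimum is
refined by *iterative* local bilinear interpolation: the search window
re-centres on the running minimum before zooming. Plain one-shot refinement
is not enough because at low $\mu_s$ and low $g$ the two prediction surfaces
form a shallow trade-off ridge along which the coarse argmin can sit a few
cells away from the true pre-image; following the ridge restores round-trip
accuracy to well below one grid cell (verified over 1000 random pairs in the
tests).

## A-scan model and fitting choices

* **Surface**: the global reflectance maximum, ties broken shallow. The five
  pixels after the peak are excluded from all fits, since the specular
  interface response does not represent subsurface scattering.
* **Segmentation**: exhaustive search for the breakpoint of a
  *continuous* two-segment linear fit to $\ln R$ vs depth; a two-segment
  model must beat a single line by a BIC margin (default 10), otherwise the
  profile is flagged single-layer. A numerically perfect single line
  short-circuits the search.
* **Deep-layer correction**: the volumetric-layer reflectivity extrapolated
  to the surface peak is divided by $(1-R_{sp})^2 e^{-2\mu_1 d_1}$ — the
  specular interface is crossed twice and the superficial layer attenuates
  the round trip. The synthetic generator applies the exact inverse of this
  factor, making the pair an exact forward–inverse round trip in the
  noise-free limit.
* **Noise floor**: profiles from the generator carry the clip level implied
  by the instrument background scan; when no floor is known,
  `estimate_noise_floor()` uses median + 3 MAD of the deepest decile.
  Points at or below the floor are excluded from all fits.
* **Aggregation**: per-sample medians, never means — single-scan estimates
  fluctuate strongly under speckle, and medians reject those outliers.

## What the synthetic A-scans emulate (and what they do not)

`simulate_ascan()` produces a single-pixel specular spike convolved with a
2-pixel-FWHM Gaussian axial PSF, two exponential layers in the Eq.-2 sense,
multiplicative unit-mean exponential speckle, and a count-floor clip. Speckle
is incoherently compounded over `n_avg = 16` realisations by default: real
analyses average many adjacent A-scans per region of interest (instrument
sessions collect >1500 scans per sample), and fully developed single-look
speckle (log-variance $\pi^2/6$) would make per-profile fitting meaningless.
The default layer amplitudes make $\ln R$ continuous at the transition, as
measured profiles show a slope change rather than a step. Not emulated:
depth-dependent sensitivity roll-off (the instrument focuses at the surface),
speckle correlation between pixels, refractive-index dispersion, or tissue
layers. Passing recovery tests therefore demonstrate correctness of the
estimator under this noise model, not performance on arbitrary raw data.

## Geometry and transport choices

* **Coordinates**: voxel indices are column-major with the z axis pointing
  *down* into the skeleton; the top face is minimum z, matching OCT depth.
* **Voxelization**: a voxel is solid when its centre is inside the mesh
  (vertical ray parity); this rule is resolution-convergent and reproduces
  analytic volumes to <0.1% at 300 px/cm on the test fixtures.
* **Layer split**: exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher, separable, in C++); skeleton voxels within
  100 µm of any non-skeleton voxel are superficial. At 300 px/cm the shell is
  exactly 3 voxels.
* **Water**: the grid is padded so 100 slabs of water sit above the highest
  skeleton voxel, then a 6-connected flood fill from the top face labels all
  reachable background as water — grooves and overhung pockets open to the
  water column fill, enclosed pores do not. (A conformal alternative was
  considered; the flood-filled slab is deterministic and matches how a
  sample sits under a water column.)
* **Boundaries**: lateral, bottom and top grid faces absorb; escaping weight
  is tallied per face. Periodic boundaries were rejected to avoid artificial
  cyclic brightening. Transport is matched-index by default (a uniform
  refractive map, as in mcxyz practice); the water optical properties default
  to $\mu_a = 0.0425$, $\mu_s = 0.001$ mm⁻¹, $g = 0$ at 930 nm and are
  configurable.
* **Scoring**: $\Phi = $ deposited energy $/(\mu_a V)$, normalised to the
  incident irradiance over the illuminated footprint so $\Phi = 1$ is the
  incident level; a $\mu_a$ floor of 0.01 mm⁻¹ (the skeleton value) keeps
  the estimator defined. Energy is conserved to $10^{-13}$ with explicit
  Russian-roulette bookkeeping.
* **RNG**: xoshiro256++ seeded per photon through splitmix64, so runs are
  bit-reproducible for a given seed and independent of R's RNG state.

## Statistical conventions

Quantiles use the type-7 rule (linear interpolation of order statistics).
Kurtosis is reported non-excess (normal = 3) with the excess variant
alongside, since the tabulation convention in the field is not fixed.
Hedges' $g$ uses $J = 1 - 3/(4\,\mathrm{df} - 1)$; the bootstrap CI is
percentile by default (BCa available) with 5000 resamples at the reporting
scale. The permutation test is a transparent block-permutation surrogate for
a mixed-effects permutational analysis: depth is a colony-level label, so
labels permute across whole colonies, never within, with the difference of
group medians as the default statistic and the add-one rule
$p = (1 + \#\{|T^*| \ge |T|\})/(n_{perm}+1)$. It is documented as an
approximation, not a reconstruction of any particular mixed-model package.

## Preset geometries

The two procedural presets encode the qualitative shallow-vs-mesophotic
contrast: shallow plates have deeper, more closely spaced corallite cups
(0.9 mm deep, 2.9 mm spacing) and denser spines (4 mm⁻²) than mesophotic
plates (0.45 mm, 3.3 mm, 2.5 mm⁻²), with columella bosses, radial septa and
coenosteum grooves in both. These dimensions are synthetic plumbing chosen
once to make the rugosity contrast reproducible; they are labelled synthetic
throughout and are not measurements.

## Problem sizes and determinism

The shipped analyses and tests use desk-scale sizes chosen as the package's
defaults: 200-replicate recovery ensembles, a 200×200 inversion grid with
1000 round-trip draws, $10^6$ photons for transport checks and end-to-end
preset runs on 6 mm plates at 150 px/cm, 1000 null datasets with 1000
bootstrap resamples (group size 30) for CI coverage, and 400×199
permutations for null uniformity. The study-scale values (75×10⁶ photons,
300 px/cm, 5000 resamples, 999 permutations) are plain configuration
parameters. Every stochastic step takes an explicit seed.

## Known limitations

* The HG-derived collection factors honour only the published endpoint
  anchors; absolute $\mu_s$–$g$ placements inherit any deviation of the true
  instrument factors from the HG shape (the CSV hook exists for exactly this
  reason).
* Simulated diffuse reflectance of thin voxel plates is much lower than
  integrating-sphere measurements on real skeletons, because real samples
  are thicker and the absorbing bottom boundary removes transmitted light;
  only directional contrasts (mesophotic > shallow) are meaningful at this
  scale.
* The permutation surrogate treats colonies as exchangeable units; with five
  colonies per depth the attainable p-value resolution is coarse, exactly as
  in the study design it mirrors.
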