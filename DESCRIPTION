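Package: coraloptics
Title: Bio-Optical Analysis of Coral Skeletons from OCT and Voxel Monte Carlo Light Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts depth-resolved inherent optical properties (scattering
    coefficient and anisotropy) of coral skeletons from optical coherence
    tomography (OCT) reflectance profiles, builds layered voxel models from
    triangulated skeletal surface meshes, simulates light fluence with a
    voxel-based Monte Carlo photon transport engine, and provides the
    downstream fluence, rugosity and group-comparison statistics. Includes a
    synthetic-data generator for two-layer A-scans, nanoparticle calibration
    phantoms and coral-like surface geometries so the whole pipeline can be
    exercised without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
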