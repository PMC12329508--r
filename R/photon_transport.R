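#' Monte Carlo simulation configuration
#'
#' @param n_photons Number of photon packets (the study-scale value is
#'   75e6; 1e6 is a practical desk default).
#' @param wavelength_nm Wavelength, nm (930; informational -- properties are
#'   supplied per label).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param roulette_threshold Weight below which Russian roulette is played.
#' @param roulette_survival Survival probability of the roulette.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_photons = 1e6, wavelength_nm = 930, seed = 1,
                              roulette_threshold = 1e-4,
                              roulette_survival = 0.1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (wavelength_nm <= 0) stop("wavelength must be > 0")
  structure(list(n_photons = n_photons, wavelength_nm = wavelength_nm,
                 seed = seed, roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "simulation_config")
}

#' Run the voxel Monte Carlo light-transport simulation
#'
#' Photons are launched collimated along +z (normal incidence), uniformly
#' over the grid's top face, and tracked through the labelled voxel grid
#' with the optical properties assigned to each label. Each interaction
#' deposits `W mu_a / mu_t` in the local voxel; scattering directions follow
#' the Henyey--Greenstein phase function with the local anisotropy; the
#' lateral, bottom and top grid boundaries absorb (escaping weight is tallied
#' by face). Transport is matched-index (no interface Fresnel events), the
#' mcxyz convention when a uniform refractive index is mapped.
#'
#' The fluence rate is recovered from absorbed energy:
#' `phi = deposited / (mu_a * voxel volume)`, normalised to unit incident
#' irradiance over the illuminated footprint, so `phi = 1` is the incident
#' light level.
#'
#' @param model A [voxel_model()] with a complete property map (see
#'   [assign_properties()]).
#' @param config A [simulation_config()].
#' @return A `fluence_volume`: `phi` (3-D array, incident-normalised),
#'   `absorbed_fraction`, `escaped_top_fraction` (scattered),
#'   `escaped_top_unscattered_fraction`, `escaped_other_fraction`,
#'   `roulette_net_fraction`, `n_photons`, `seed`, plus `deposited` and the
#'   per-label `mu_a` used in scoring.
#' @export
run_simulation <- function(model, config = simulation_config()) {
  if (length(model$property_map) < 1) stop("model has no property map")
  labs_present <- sort(unique(as.integer(model$labels)))
  nlab <- max(labs_present) + 1L
  mua <- numeric(nlab); mus <- numeric(nlab); gg <- numeric(nlab)
  for (l in labs_present) {
    p <- model$property_map[[as.character(l)]]
    if (is.null(p)) {
      if (l == 0L) p <- optical_properties(0, 0, 0, 1)
      else stop(sprintf("label %d has no assigned optical properties", l))
    }
    mua[l + 1] <- p$mu_a; mus[l + 1] <- p$mu_s; gg[l + 1] <- p$g
  }
  if (all(dim(model$labels) < 2)) stop("zero-thickness model")
  res <- .mc_transport(as.integer(model$labels), dim(model$labels),
                       model$pitch_mm, mua, mus, gg,
                       as.double(config$n_photons), as.double(config$seed),
                       config$roulette_threshold, config$roulette_survival)
  d <- dim(model$labels)
  dep <- array(res$deposited, dim = d)
  ## incident irradiance: n_photons spread over the top-face area
  vox_vol <- model$pitch_mm^3
  footprint <- d[1] * d[2] * model$pitch_mm^2
  irr <- config$n_photons / footprint
  mua_vox <- array(mua[as.integer(model$labels) + 1L], dim = d)
  phi <- array(0, dim = d)
  ok <- mua_vox > 0
  phi[ok] <- dep[ok] / (mua_vox[ok] * vox_vol * irr)
  np <- res$n_photons
  structure(list(
    phi = phi,
    deposited = dep,
    mu_a_by_label = mua,
    absorbed_fraction = res$absorbed / np,
    escaped_top_fraction = res$escaped_top_scattered / np,
    escaped_top_unscattered_fraction = res$escaped_top_unscattered / np,
    escaped_other_fraction = res$escaped_other / np,
    roulette_net_fraction = res$roulette_net / np,
    n_photons = np, seed = config$seed), class = "fluence_volume")
}

#' Sample Henyey--Greenstein deflection cosines
#'
#' Inverse-CDF sampling of the scattering deflection angle cosine for
#' anisotropy `g`; `g = 0` reduces to the uniform (isotropic) distribution.
#' The sample mean converges to `g` (the anisotropy *is* the mean cosine).
#'
#' @param n Number of draws (uses R's RNG stream).
#' @param g Anisotropy in `[0, 1)`.
#' @return Vector of cosines in `[-1, 1]`.
#' @export
sample_hg_deflection <- function(n, g) {
  if (g < 0 || g >= 1) stop("g must lie in [0, 1)")
  u <- stats::runif(n)
  if (g < 1e-8) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Diffuse reflectance from a completed simulation
#'
#' The fraction of incident light escaping back through the illuminated top
#' face after at least one scattering event (the unscattered specular
#' component is excluded).
#'
#' @param fluence A [run_simulation()] result.
#' @return `R_d` in `[0, 1]`.
#' @export
diffuse_reflectance <- function(fluence) {
  fluence$escaped_top_fraction
}
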