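#' Specification of a synthetic two-layer A-scan
#'
#' Describes the forward model that generates an OCT depth profile with the
#' statistical structure the fitting assumes: a strong single-pixel specular
#' surface peak (convolved with a 2-pixel Gaussian axial PSF), a highly
#' scattering superficial layer, a more transmissive volumetric layer whose
#' amplitude is attenuated by the overlying layer and the `(1 - R_sp)^2`
#' interface round trip (the exact inverse of [correct_deep_layer()]),
#' optional fully developed speckle (unit-mean exponential multiplicative
#' noise, incoherently averaged over `n_avg` realisations), and a count
#' noise floor.
#'
#' @param rho1,mu1 Superficial-layer reflectivity and one-way attenuation
#'   (mm^-1).
#' @param d1_mm Superficial-layer thickness, mm.
#' @param rho2,mu2 Volumetric-layer reflectivity and attenuation.
#' @param r_sp Specular reflectance of the surface interface.
#' @param speckle Logical: apply multiplicative speckle noise.
#' @param n_avg Number of incoherently averaged speckle realisations
#'   (OCT practice averages many adjacent A-scans per region of interest).
#' @param calibration A [fit_signal_calibration()]-style list `(intercept_a,
#'   slope_b)` encoding counts = a + b ln R.
#' @param noise_floor_counts Counts below which the signal is clipped.
#' @param pitch_mm Axial pixel pitch, mm.
#' @param n_pixels Number of axial pixels (>= 64).
#' @param surface_index Pixel index of the surface peak.
#' @return An `ascan_spec` list.
#' @export
ascan_spec <- function(rho1 = 1.2e-6, mu1 = 40, d1_mm = 0.1,
                       rho2 = 2.3e-6, mu2 = 3,
                       r_sp = 0.02, speckle = TRUE, n_avg = 16,
                       calibration = list(intercept_a = 520, slope_b = 12),
                       noise_floor_counts = 180,
                       pitch_mm = 2 / 681, n_pixels = 681,
                       surface_index = 40) {
  if (rho1 <= 0 || rho2 <= 0 || mu1 <= 0 || mu2 <= 0) stop("rho and mu must be > 0")
  if (d1_mm <= 0) stop("layer-1 thickness must be > 0")
  if (n_pixels < 64) stop("n_pixels must be >= 64")
  if (r_sp < 0 || r_sp >= 1) stop("r_sp must lie in [0, 1)")
  structure(list(rho1 = rho1, mu1 = mu1, d1_mm = d1_mm, rho2 = rho2,
                 mu2 = mu2, r_sp = r_sp, speckle = speckle, n_avg = n_avg,
                 calibration = calibration,
                 noise_floor_counts = noise_floor_counts,
                 pitch_mm = pitch_mm, n_pixels = n_pixels,
                 surface_index = as.integer(surface_index)),
            class = "ascan_spec")
}

#' Simulate a synthetic OCT A-scan
#'
#' @param spec An [ascan_spec()].
#' @param seed Optional integer seed (deterministic profile under a fixed
#'   seed).
#' @return List with `counts`, `depth_mm`, the noise-free `reflectance`, and
#'   `truth` (the generating parameters, for recovery tests).
#' @export
simulate_ascan <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_pixels
  z <- (seq_len(n) - 1) * spec$pitch_mm
  z0 <- z[spec$surface_index]
  zr <- z - z0
  r <- rep(0, n)
  in1 <- zr > 0 & zr <= spec$d1_mm
  in2 <- zr > spec$d1_mm
  r[in1] <- spec$rho1 * exp(-2 * spec$mu1 * zr[in1])
  amp2 <- spec$rho2 * (1 - spec$r_sp)^2 * exp(-2 * spec$mu1 * spec$d1_mm)
  r[in2] <- amp2 * exp(-2 * spec$mu2 * zr[in2])
  ## specular spike: single pixel of amplitude r_sp, 2-pixel Gaussian PSF
  spike <- rep(0, n)
  spike[spec$surface_index] <- spec$r_sp
  k <- stats::dnorm(-4:4, sd = 0.85)  # 2-pixel FWHM axial PSF
  k <- k / sum(k)
  spike <- stats::filter(spike, k, sides = 2)
  spike[is.na(spike)] <- 0
  r_clean <- r + as.numeric(spike)
  r_noisy <- r_clean
  if (spec$speckle) {
    ## unit-mean exponential speckle, incoherently compounded n_avg times
    s <- stats::rgamma(n, shape = spec$n_avg, rate = spec$n_avg)
    r_noisy <- r_clean * s
  }
  counts <- spec$calibration$intercept_a +
    spec$calibration$slope_b * log(pmax(r_noisy, 1e-300))
  counts <- pmax(counts, spec$noise_floor_counts)
  list(counts = counts, depth_mm = z, reflectance = r_clean,
       truth = list(rho1 = spec$rho1, mu1 = spec$mu1, d1_mm = spec$d1_mm,
                    rho2 = spec$rho2, mu2 = spec$mu2, r_sp = spec$r_sp,
                    surface_index = spec$surface_index,
                    calibration = spec$calibration))
}

#' Simulated A-scan as an [ascan_profile()]
#'
#' Convenience wrapper: generate, convert counts back to reflectance with the
#' same calibration, and wrap with surface detection and noise-floor
#' estimation -- the profile the fitting pipeline sees.
#'
#' @param spec An [ascan_spec()].
#' @param seed Optional seed.
#' @return List with `profile` (an `ascan_profile`) and `truth`.
#' @export
simulate_ascan_profile <- function(spec, seed = NULL) {
  sim <- simulate_ascan(spec, seed = seed)
  refl <- counts_to_reflectance(sim$counts, spec$calibration)
  ## the clip level is known from the instrument background scan, so the
  ## profile carries it directly instead of re-estimating it from the tail
  floor_r <- counts_to_reflectance(spec$noise_floor_counts, spec$calibration)
  list(profile = ascan_profile(sim$depth_mm, refl, noise_floor = floor_r),
       truth = sim$truth)
}

#' Generate a nanoparticle calibration phantom series
#'
#' Monodisperse 100 nm polystyrene spheres (n = 1.59) in water across five
#' concentrations spanning 2.84e12 to 4.55e13 spheres per mL (log-spaced by
#' default). For each concentration the Mie-theoretical `(mu_s, g)` is
#' computed, mapped through the forward model to `(mu, rho)`, and a
#' single-layer A-scan is simulated, so the measured attenuation-vs-
#' concentration curve can be validated against theory.
#'
#' @param concentrations Spheres per mL (default: 5 log-spaced points over
#'   the standard range).
#' @param diameter_nm,n_particle Particle diameter and index.
#' @param instrument An [instrument_constants()] object.
#' @param table Collection-factor table.
#' @param mu_a Background absorption of the suspension, mm^-1.
#' @param speckle Logical: speckle noise on the simulated scans.
#' @param seed Optional seed.
#' @return List with `theory` (data frame: concentration, mu_s, g, mu, rho)
#'   and `scans` (list of simulated profiles with truths).
#' @export
make_phantom_series <- function(concentrations = NULL,
                                diameter_nm = 100, n_particle = 1.59,
                                instrument = instrument_constants(),
                                table = hg_collection_table(instrument$na),
                                mu_a = 0.01, speckle = TRUE, seed = NULL) {
  if (is.null(concentrations))
    concentrations <- exp(seq(log(2.84e12), log(4.55e13), length.out = 5))
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_medium <- 1.33
  theory <- do.call(rbind, lapply(concentrations, function(cc) {
    mp <- mie_phantom_properties(diameter_nm, n_particle, n_medium,
                                 instrument$wavelength_nm, cc)
    props <- optical_properties(mu_a = mu_a, mu_s = mp$mu_s, g = mp$g)
    data.frame(concentration = cc, mu_s = mp$mu_s, g = mp$g,
               mu = forward_attenuation(props, table),
               rho = forward_reflectivity(props, instrument$l_cg_water, table))
  }))
  scans <- lapply(seq_len(nrow(theory)), function(i) {
    ## single-layer suspension: both layers share the phantom's (rho, mu)
    rho <- max(theory$rho[i], 1e-12)
    sp <- ascan_spec(rho1 = rho, mu1 = max(theory$mu[i], 1e-6),
                     d1_mm = 0.6, rho2 = rho, mu2 = max(theory$mu[i], 1e-6),
                     r_sp = 0.004, speckle = speckle,
                     pitch_mm = instrument$pitch_mm,
                     n_pixels = instrument$n_z_pixels)
    simulate_ascan_profile(sp)
  })
  list(theory = theory, scans = scans)
}

#' Specification of a procedural coral-like surface geometry
#'
#' Height-field plate with periodic corallite cups (each with a central
#' columella boss and radial septal ridges), connecting coenosteum grooves,
#' and randomly placed coenosteum spines. Two presets mirror the qualitative
#' shallow-vs-mesophotic contrast: shallow corallites have deeper, denser
#' relief than mesophotic ones. All dimensions are synthetic defaults chosen
#' to emulate reef-coral microstructure, not measurements.
#'
#' @param preset `"shallow"` or `"mesophotic"`.
#' @param plate_mm Plate edge length, mm.
#' @param thickness_mm Plate thickness, mm.
#' @param cup_radius_mm,cup_depth_mm Corallite cup radius / depth, mm.
#' @param cup_spacing_mm Corallite lattice spacing, mm (> cup diameter).
#' @param columella_frac Columella boss height as a fraction of cup depth.
#' @param septa_n,septa_amp_mm Number of radial septal ridges and their
#'   amplitude.
#' @param spine_density_mm2 Spines per mm^2 of coenosteum.
#' @param spine_height_mm,spine_sigma_mm Spine height and lateral width.
#' @param groove_depth_mm,groove_width_mm Coenosteum groove depth / width.
#' @param grid_mm Height-field sampling pitch, mm.
#' @param seed Integer seed (meshes are deterministic under seed).
#' @return A `coral_geometry_spec` list.
#' @export
coral_geometry_spec <- function(preset = c("shallow", "mesophotic"),
                                plate_mm = 10, thickness_mm = 2,
                                cup_radius_mm = NULL, cup_depth_mm = NULL,
                                cup_spacing_mm = NULL,
                                columella_frac = 0.45,
                                septa_n = 12, septa_amp_mm = NULL,
                                spine_density_mm2 = NULL,
                                spine_height_mm = NULL, spine_sigma_mm = 0.09,
                                groove_depth_mm = NULL, groove_width_mm = NULL,
                                grid_mm = 0.05, seed = 1) {
  preset <- match.arg(preset)
  def <- if (preset == "shallow") {
    list(cup_radius_mm = 1.1, cup_depth_mm = 0.9, cup_spacing_mm = 2.9,
         septa_amp_mm = 0.15, spine_density_mm2 = 4,
         spine_height_mm = 0.12, groove_depth_mm = 0.25, groove_width_mm = 0.35)
  } else {
    list(cup_radius_mm = 1.0, cup_depth_mm = 0.45, cup_spacing_mm = 3.3,
         septa_amp_mm = 0.12, spine_density_mm2 = 2.5,
         spine_height_mm = 0.10, groove_depth_mm = 0.20, groove_width_mm = 0.40)
  }
  take <- function(x, d) if (is.null(x)) d else x
  out <- list(preset = preset, plate_mm = plate_mm, thickness_mm = thickness_mm,
              cup_radius_mm = take(cup_radius_mm, def$cup_radius_mm),
              cup_depth_mm = take(cup_depth_mm, def$cup_depth_mm),
              cup_spacing_mm = take(cup_spacing_mm, def$cup_spacing_mm),
              columella_frac = columella_frac,
              septa_n = septa_n, septa_amp_mm = take(septa_amp_mm, def$septa_amp_mm),
              spine_density_mm2 = take(spine_density_mm2, def$spine_density_mm2),
              spine_height_mm = take(spine_height_mm, def$spine_height_mm),
              spine_sigma_mm = spine_sigma_mm,
              groove_depth_mm = take(groove_depth_mm, def$groove_depth_mm),
              groove_width_mm = take(groove_width_mm, def$groove_width_mm),
              grid_mm = grid_mm, seed = seed)
  if (any(unlist(out[c("plate_mm", "thickness_mm", "grid_mm")]) <= 0))
    stop("all lengths must be > 0")
  if (out$cup_depth_mm > 0 && out$cup_spacing_mm <= 2 * out$cup_radius_mm)
    stop("corallite cups overlap: spacing must exceed the cup diameter")
  class(out) <- "coral_geometry_spec"
  out
}

#' Generate a watertight coral-like surface mesh
#'
#' Builds the height field described by a [coral_geometry_spec()], closes it
#' with side skirts and a flat bottom, and returns a watertight triangle
#' mesh in the depth-positive frame (top surface near z = 0, bottom at
#' z = thickness).
#'
#' @param spec A [coral_geometry_spec()].
#' @return A [triangle_mesh()].
#' @export
make_coral_geometry <- function(spec) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  L <- spec$plate_mm
  h <- spec$grid_mm
  xs <- seq(0, L, by = h)
  ys <- seq(0, L, by = h)
  nx <- length(xs); ny <- length(ys)
  zz <- matrix(0, nx, ny)  # z down: positive = deeper

  ## corallite cups on a square lattice (offset to keep cups inside the plate)
  s <- spec$cup_spacing_mm
  centers <- expand.grid(cx = seq(s / 2, L - s / 2 + 1e-9, by = s),
                         cy = seq(s / 2, L - s / 2 + 1e-9, by = s))
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  coen <- matrix(TRUE, nx, ny)  # coenosteum mask (outside cups)
  if (spec$cup_depth_mm > 0 && nrow(centers) > 0) {
    for (ic in seq_len(nrow(centers))) {
      dx <- X - centers$cx[ic]; dy <- Y - centers$cy[ic]
      rr <- sqrt(dx^2 + dy^2)
      inside <- rr < spec$cup_radius_mm
      if (!any(inside)) next
      rn <- rr[inside] / spec$cup_radius_mm
      cup <- spec$cup_depth_mm * (cos(rn * pi / 2))^2
      ## columella: central boss rising from the cup floor
      col_h <- spec$columella_frac * spec$cup_depth_mm *
        exp(-(rn / 0.25)^2)
      ## septa: radial ridges rising toward the rim
      th <- atan2(dy[inside], dx[inside])
      sep <- spec$septa_amp_mm * pmax(0, cos(spec$septa_n * th)) * rn *
        (rn < 0.95)
      zz[inside] <- zz[inside] + cup - col_h - sep
      coen[inside] <- FALSE
    }
  }
  ## coenosteum grooves: shallow channels along the lattice lines
  if (spec$groove_depth_mm > 0) {
    gx <- seq(0, L, by = s)
    for (g0 in gx) {
      for (D in list(abs(X - g0), abs(Y - g0))) {
        w <- spec$groove_width_mm / 2
        m <- D < 3 * w & coen
        zz[m] <- pmax(zz[m], spec$groove_depth_mm * exp(-(D[m] / w)^2))
      }
    }
  }
  ## spines: random upward bumps on the coenosteum
  n_sp <- stats::rpois(1, spec$spine_density_mm2 * L^2 * mean(coen))
  if (n_sp > 0 && spec$spine_height_mm > 0) {
    px <- stats::runif(n_sp, 0, L)
    py <- stats::runif(n_sp, 0, L)
    for (ip in seq_len(n_sp)) {
      i0 <- which(xs >= px[ip] - 4 * spec$spine_sigma_mm &
                    xs <= px[ip] + 4 * spec$spine_sigma_mm)
      j0 <- which(ys >= py[ip] - 4 * spec$spine_sigma_mm &
                    ys <= py[ip] + 4 * spec$spine_sigma_mm)
      if (length(i0) == 0 || length(j0) == 0) next
      dd <- outer((xs[i0] - px[ip])^2, (ys[j0] - py[ip])^2, "+")
      bump <- spec$spine_height_mm * exp(-dd / (2 * spec$spine_sigma_mm^2))
      keep <- coen[i0, j0, drop = FALSE]
      zz[i0, j0] <- zz[i0, j0] - bump * keep
    }
  }
  ## keep the surface above the bottom plate
  zz <- pmin(zz, spec$thickness_mm - 0.2)
  heightfield_mesh(xs, ys, zz, bottom_z = spec$thickness_mm)
}

#' Triangulate a height field into a watertight plate mesh
#'
#' @param xs,ys Grid coordinates, mm.
#' @param zz Surface depth matrix (`length(xs)` x `length(ys)`, z down).
#' @param bottom_z Depth of the flat bottom face, mm (> max(zz)).
#' @return A watertight [triangle_mesh()].
#' @export
heightfield_mesh <- function(xs, ys, zz, bottom_z) {
  nx <- length(xs); ny <- length(ys)
  stopifnot(nrow(zz) == nx, ncol(zz) == ny, bottom_z > max(zz))
  vid <- function(i, j) (j - 1) * nx + i
  verts <- cbind(rep(xs, ny), rep(ys, each = nx), as.vector(zz))
  faces <- vector("list", 4)
  ## top surface: wind so outward normal points up (-z)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- vid(i, j); v10 <- vid(i + 1, j); v01 <- vid(i, j + 1); v11 <- vid(i + 1, j + 1)
  faces[[1]] <- rbind(cbind(v00, v01, v10), cbind(v10, v01, v11))
  ## bottom perimeter vertices
  per <- c(vid(seq_len(nx), 1),
           vid(nx, seq(2, ny)),
           vid(seq(nx - 1, 1), ny),
           vid(1, seq(ny - 1, 2)))
  nper <- length(per)
  bstart <- nrow(verts)
  verts <- rbind(verts, cbind(verts[per, 1], verts[per, 2], bottom_z))
  bid <- bstart + seq_len(nper)
  nxt <- c(seq(2, nper), 1)
  ## side skirt: outward normals away from the plate
  faces[[2]] <- rbind(cbind(per, bid, per[nxt]),
                      cbind(per[nxt], bid, bid[nxt]))
  ## bottom: triangle fan over the (convex) perimeter
  k <- seq(2, nper - 1)
  faces[[3]] <- cbind(bid[1], bid[k], bid[k + 1])
  m <- triangle_mesh(verts, do.call(rbind, faces[1:3]))
  repair_mesh(m)
}
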