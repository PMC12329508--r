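#' Fit the OCT signal calibration
#'
#' The spectrometer records a log-encoded signal, `OCT(z) = a + b ln R(z)`.
#' The intercept `a` and slope `b` are estimated by least squares from
#' reference interfaces of known Fresnel reflectance (glass/air, glass/water,
#' glass/oil) and the nanoparticle calibration series.
#'
#' @param reflectance Known reflectances of the reference interfaces (> 0).
#' @param counts Measured signal at each interface, counts.
#' @return A `signal_calibration` list with `intercept_a`, `slope_b` and the
#'   regression `r2`.
#' @export
fit_signal_calibration <- function(reflectance, counts) {
  if (length(reflectance) != length(counts))
    stop("reflectance and counts must have equal length")
  if (any(reflectance <= 0)) stop("reference reflectances must be > 0")
  if (length(unique(reflectance)) < 2)
    stop("need at least 2 reference points with distinct reflectances")
  fit <- stats::lm.fit(cbind(1, log(reflectance)), counts)
  b <- unname(fit$coefficients[2])
  if (!is.finite(b) || b <= 0) stop("calibration slope must be positive")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((counts - mean(counts))^2)
  structure(list(intercept_a = unname(fit$coefficients[1]), slope_b = b,
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "signal_calibration")
}

#' Convert raw OCT counts to calibrated reflectance
#'
#' Inverts the log-encoding: `R = exp((counts - a) / b)`.
#'
#' @param counts Raw signal, counts.
#' @param calibration A [fit_signal_calibration()] result (or list with
#'   `intercept_a`, `slope_b`).
#' @return Reflectance values, strictly positive.
#' @export
counts_to_reflectance <- function(counts, calibration) {
  if (calibration$slope_b <= 0) stop("calibration slope must be positive")
  exp((counts - calibration$intercept_a) / calibration$slope_b)
}

#' @rdname counts_to_reflectance
#' @export
reflectance_to_counts <- function(reflectance, calibration) {
  calibration$intercept_a + calibration$slope_b * log(reflectance)
}

#' Detect the skeletal surface in an A-scan
#'
#' The surface is the position of maximum reflectance (the specular peak at
#' the air--skeleton interface); ties break toward the shallowest index.
#'
#' @param reflectance Reflectance profile.
#' @return Integer index of the surface pixel.
#' @export
detect_surface <- function(reflectance) {
  if (length(reflectance) == 0) stop("empty profile")
  if (diff(range(reflectance)) == 0) stop("flat profile: no surface peak")
  which.max(reflectance)
}

#' Estimate the noise floor of a reflectance profile
#'
#' Robust floor from the deepest `tail_frac` of the profile:
#' `median + 3 MAD`. Points at or below the floor are excluded from fits.
#'
#' @param reflectance Reflectance profile.
#' @param tail_frac Fraction of the deepest samples used.
#' @return Noise floor on the reflectance scale.
#' @export
estimate_noise_floor <- function(reflectance, tail_frac = 0.1) {
  n <- length(reflectance)
  tail <- reflectance[max(1, ceiling(n * (1 - tail_frac))):n]
  stats::median(tail) + 3 * stats::mad(tail)
}

#' Assemble an A-scan profile object
#'
#' @param depth_mm Strictly increasing, uniformly pitched depth axis, mm.
#' @param reflectance Calibrated reflectance `R(z)`, >= 0.
#' @param surface_index Surface pixel (default: detected).
#' @param noise_floor Reflectance noise floor (default: estimated).
#' @return An `ascan_profile` list.
#' @export
ascan_profile <- function(depth_mm, reflectance,
                          surface_index = detect_surface(reflectance),
                          noise_floor = estimate_noise_floor(reflectance)) {
  stopifnot(length(depth_mm) == length(reflectance))
  d <- diff(depth_mm)
  if (any(d <= 0) || diff(range(d)) > 1e-9 * mean(d))
    stop("depth axis must be strictly increasing with uniform pitch")
  if (any(reflectance < 0)) stop("reflectance must be >= 0")
  if (surface_index < 1 || surface_index > length(reflectance))
    stop("surface index out of bounds")
  structure(list(depth_mm = depth_mm, reflectance = reflectance,
                 surface_index = surface_index, noise_floor = noise_floor),
            class = "ascan_profile")
}

#' Fit one exponential layer of an A-scan
#'
#' Least-squares line through `ln R` vs depth over `[z_start, z_end]`
#' (depths relative to the surface peak). The round-trip decay gives the
#' one-way attenuation `mu = -slope / 2`; the local reflectivity `rho` is the
#' fitted value extrapolated to the surface-peak depth. When the window abuts
#' the surface peak, the first `n_exclude` pixels after the peak are dropped
#' because the specular interface response does not represent subsurface
#' scattering.
#'
#' @param profile An [ascan_profile()].
#' @param z_start,z_end Window below the surface, mm (relative to the peak).
#' @param n_exclude Pixels excluded after the surface peak (default 5).
#' @param min_points Minimum usable points in the window.
#' @return List with `rho`, `mu` (mm^-1), `r2` and `n_points`.
#' @export
fit_layer <- function(profile, z_start, z_end, n_exclude = 5, min_points = 5) {
  z0 <- profile$depth_mm[profile$surface_index]
  zrel <- profile$depth_mm - z0
  win <- which(zrel >= z_start & zrel <= z_end &
                 seq_along(zrel) > profile$surface_index)
  ## specular-peak exclusion; no-op for windows that start deeper
  win <- win[win > profile$surface_index + n_exclude]
  if (length(win) < min_points) stop("too few points in fit window")
  idx <- win[profile$reflectance[win] > profile$noise_floor]
  if (length(idx) < min_points) stop("window is below the noise floor")
  x <- zrel[idx]
  y <- log(profile$reflectance[idx])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(rho = exp(unname(fit$coefficients[1])),
       mu = -slope / 2,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_points = length(idx))
}

#' Locate the superficial-to-volumetric layer transition
#'
#' Exhaustive search for the breakpoint of a continuous two-segment linear
#' fit to `ln R` vs depth over the usable points below the surface (after the
#' specular-peak exclusion window and above the noise floor). The breakpoint
#' minimising the total residual sum of squares is returned; if the best
#' two-segment model does not beat a single line by a BIC margin the profile
#' is flagged single-layer.
#'
#' @param profile An [ascan_profile()].
#' @param n_exclude Pixels excluded after the surface peak.
#' @param min_seg Minimum points per segment.
#' @param bic_margin Required BIC improvement of the two-segment model.
#' @return List with `transition_index` (index into the profile),
#'   `transition_depth_mm` (below the surface peak), `single_layer` flag and
#'   the two fitted slopes.
#' @export
segment_two_layers <- function(profile, n_exclude = 5, min_seg = 6,
                               bic_margin = 10) {
  usable <- which(seq_along(profile$reflectance) > profile$surface_index + n_exclude &
                    profile$reflectance > profile$noise_floor)
  if (length(usable) < 2 * min_seg)
    stop("too few usable points below the surface for segmentation")
  z0 <- profile$depth_mm[profile$surface_index]
  x <- profile$depth_mm[usable] - z0
  y <- log(profile$reflectance[usable])
  n <- length(x)

  one <- stats::lm.fit(cbind(1, x), y)
  rss1 <- sum(one$residuals^2)
  ## a numerically perfect single line needs no breakpoint
  if (rss1 / n < 1e-18) {
    return(list(transition_index = NA_integer_, transition_depth_mm = NA_real_,
                single_layer = TRUE, slopes = c(one$coefficients[2], NA_real_)))
  }

  best_rss <- Inf; best_k <- NA_integer_; best_sl <- c(NA_real_, NA_real_)
  for (k in min_seg:(n - min_seg)) {
    xb <- x[k]
    ## continuous two-segment basis: 1, x, (x - xb)_+
    hinge <- pmax(x - xb, 0)
    fit <- stats::lm.fit(cbind(1, x, hinge), y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_k <- k
      best_sl <- c(unname(fit$coefficients[2]),
                   unname(fit$coefficients[2] + fit$coefficients[3]))
    }
  }
  ## BIC with sigma profiled out; two-segment has 2 extra params (slope2, knot)
  bic1 <- n * log(rss1 / n) + 2 * log(n)
  bic2 <- n * log(max(best_rss, 1e-300) / n) + 4 * log(n)
  if (bic1 - bic2 < bic_margin) {
    return(list(transition_index = NA_integer_, transition_depth_mm = NA_real_,
                single_layer = TRUE, slopes = c(one$coefficients[2], NA_real_)))
  }
  list(transition_index = usable[best_k],
       transition_depth_mm = x[best_k],
       single_layer = FALSE,
       slopes = best_sl)
}

#' Correct the deep-layer reflectivity for overlying losses
#'
#' The raw layer-2 reflectivity (extrapolated to the surface peak) is reduced
#' by the round trip through the specular interface and the attenuating
#' superficial layer. The correction divides by
#' `(1 - R_sp)^2 exp(-2 mu1 d1)`.
#'
#' @param rho2_raw Raw volumetric-layer reflectivity.
#' @param mu1 Superficial-layer one-way attenuation, mm^-1.
#' @param d1 Superficial-layer thickness, mm.
#' @param r_sp Specular reflectance of the surface interface, in `[0, 1)`.
#' @return Corrected reflectivity (correction factor >= 1).
#' @export
correct_deep_layer <- function(rho2_raw, mu1, d1, r_sp) {
  if (d1 <= 0) stop("layer thickness must be > 0")
  if (r_sp < 0 || r_sp >= 1) stop("specular reflectance must lie in [0, 1)")
  if (mu1 < 0) stop("attenuation must be >= 0")
  rho2_raw / ((1 - r_sp)^2 * exp(-2 * mu1 * d1))
}

#' Fit the full two-layer model to an A-scan
#'
#' Pipeline: detect the surface, segment into superficial and volumetric
#' layers, fit each layer (Eq. `R(z) = rho exp(-2 mu z)` in log space), and
#' correct the volumetric-layer reflectivity for the specular interface and
#' superficial attenuation.
#'
#' @param profile An [ascan_profile()].
#' @param r_sp Specular reflectance of the surface interface used in the
#'   deep-layer correction (default: air/aragonite-like interface estimated
#'   from the surface peak is *not* attempted; pass the calibrated value).
#' @param n_exclude Pixels excluded after the surface peak.
#' @return A `layer_fit_result` list: `rho_superficial`, `mu_superficial`,
#'   `rho_volumetric` (corrected), `mu_volumetric`, `transition_depth_mm`,
#'   `r2_superficial`, `r2_volumetric`, `single_layer`.
#' @export
fit_ascan <- function(profile, r_sp = 0, n_exclude = 5) {
  seg <- segment_two_layers(profile, n_exclude = n_exclude)
  z0 <- profile$depth_mm[profile$surface_index]
  zmax <- max(profile$depth_mm) - z0
  if (seg$single_layer) {
    f <- fit_layer(profile, 0, zmax, n_exclude = n_exclude)
    return(structure(list(rho_superficial = f$rho, mu_superficial = f$mu,
                          rho_volumetric = NA_real_, mu_volumetric = NA_real_,
                          transition_depth_mm = NA_real_,
                          r2_superficial = f$r2, r2_volumetric = NA_real_,
                          single_layer = TRUE), class = "layer_fit_result"))
  }
  d1 <- seg$transition_depth_mm
  f1 <- fit_layer(profile, 0, d1, n_exclude = n_exclude)
  f2 <- fit_layer(profile, d1, zmax, n_exclude = n_exclude, min_points = 5)
  rho2 <- correct_deep_layer(f2$rho, f1$mu, d1, r_sp)
  structure(list(rho_superficial = f1$rho, mu_superficial = f1$mu,
                 rho_volumetric = rho2, mu_volumetric = f2$mu,
                 transition_depth_mm = d1,
                 r2_superficial = f1$r2, r2_volumetric = f2$r2,
                 single_layer = FALSE), class = "layer_fit_result")
}

#' Read A-scans from CSV
#'
#' Expects columns `depth_index,counts` (one A-scan) or
#' `scan_id,depth_index,counts` (many). Depth is derived from the instrument's
#' axial pitch; when scans were recorded in air, `medium_n` rescales optical
#' to physical depth.
#'
#' @param path CSV file.
#' @param calibration A [fit_signal_calibration()] result.
#' @param instrument An [instrument_constants()] object.
#' @param medium_n Refractive-index divisor for the depth axis (1.0 for air).
#' @return A list of [ascan_profile()] objects.
#' @export
read_ascan_csv <- function(path, calibration, instrument = instrument_constants(),
                           medium_n = 1.0) {
  df <- utils::read.csv(path)
  if (!"counts" %in% names(df)) stop("CSV must have a 'counts' column")
  split_ids <- if ("scan_id" %in% names(df)) df$scan_id else rep(1L, nrow(df))
  lapply(split(df, split_ids), function(d) {
    d <- d[order(d$depth_index), ]
    z <- d$depth_index * instrument$pitch_mm / medium_n
    ascan_profile(z, counts_to_reflectance(d$counts, calibration))
  })
}
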