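#' Construct a set of inherent optical properties
#'
#' Bundles the four quantities assigned to a voxel label or inverted from an
#' OCT layer fit: the absorption coefficient `mu_a`, the scattering
#' coefficient `mu_s` (both in mm^-1, probability of an event per unit path
#' length), the scattering anisotropy `g` (mean cosine of the single-scattering
#' deflection angle) and the refractive index `n`.
#'
#' @param mu_a Absorption coefficient, mm^-1. Defaults to 0.01 mm^-1, the
#'   value attributed to residual water in bare aragonite skeleton at 930 nm.
#' @param mu_s Scattering coefficient, mm^-1.
#' @param g Scattering anisotropy, dimensionless, in `[0, 1)`.
#' @param n Refractive index, >= 1.
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a = 0.01, mu_s = 0, g = 0, n = 1.33) {
  stopifnot(length(mu_a) == 1, length(mu_s) == 1, length(g) == 1, length(n) == 1)
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("mu_s must be >= 0")
  if (!is.finite(g) || g < 0 || g >= 1) stop("g must lie in [0, 1)")
  if (!is.finite(n) || n < 0.999) stop("n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g /mm, mu_s = %g /mm, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' OCT instrument constants
#'
#' Spectral-domain OCT system constants used throughout the fitting and
#' inversion: numerical aperture, coherence-gate lengths in air and water,
#' centre wavelength, axial field of view and axial pixel count. The defaults
#' describe a 930 nm system with NA 0.075, coherence length 5.5 um in air and
#' 4.1 um in water, and a 2 mm axial field sampled by 681 pixels.
#'
#' @param na Numerical aperture, in (0, 1).
#' @param l_cg_air,l_cg_water Coherence-gate lengths, mm.
#' @param wavelength_nm Centre wavelength, nm.
#' @param z_fov_mm Axial field of view, mm.
#' @param n_z_pixels Axial pixel count.
#' @return An object of class `instrument_constants` with the derived axial
#'   pixel pitch in `pitch_mm` (= `z_fov_mm / n_z_pixels`).
#' @export
instrument_constants <- function(na = 0.075,
                                 l_cg_air = 0.0055,
                                 l_cg_water = 0.0041,
                                 wavelength_nm = 930,
                                 z_fov_mm = 2,
                                 n_z_pixels = 681) {
  if (na <= 0 || na >= 1) stop("numerical aperture must lie in (0, 1)")
  if (l_cg_air <= 0 || l_cg_water <= 0) stop("coherence-gate lengths must be > 0")
  if (wavelength_nm <= 0) stop("wavelength must be > 0")
  if (z_fov_mm <= 0 || n_z_pixels < 1) stop("invalid axial field")
  structure(list(na = na, l_cg_air = l_cg_air, l_cg_water = l_cg_water,
                 wavelength_nm = wavelength_nm, z_fov_mm = z_fov_mm,
                 n_z_pixels = n_z_pixels,
                 pitch_mm = z_fov_mm / n_z_pixels),
            class = "instrument_constants")
}

#' Fresnel specular reflectance at normal incidence
#'
#' Reflectance of a planar interface between media of refractive indices `n1`
#' and `n2` for normally incident light, `((n1 - n2) / (n1 + n2))^2`. Used to
#' calibrate the OCT signal against known glass/air, glass/water and glass/oil
#' interfaces.
#'
#' @param n1,n2 Refractive indices (>= 1; exactly 1.0 admitted for air).
#' @return Reflectance fraction in `[0, 1)`.
#' @export
fresnel_specular_reflectance <- function(n1, n2) {
  if (any(!is.finite(n1)) || any(!is.finite(n2)) || any(n1 < 0.999) || any(n2 < 0.999))
    stop("refractive indices must be >= 1")
  ((n1 - n2) / (n1 + n2))^2
}

## ---- Mie theory -----------------------------------------------------------

#' Mie scattering coefficients for a homogeneous sphere
#'
#' Bohren--Huffman Mie coefficients a_n, b_n computed with the logarithmic-
#' derivative downward recursion, truncated at the Wiscombe order
#' `x + 4 x^(1/3) + 2`.
#'
#' @param m Relative refractive index (particle / medium), real.
#' @param x Size parameter `2 pi r n_medium / wavelength`.
#' @return List with complex vectors `a`, `b` and the order vector `n`.
#' @keywords internal
mie_coefficients <- function(m, x) {
  if (x <= 0) stop("size parameter must be > 0")
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- seq_len(nmax)
  mx <- m * x
  ## logarithmic derivative D_n(mx) by downward recursion
  nstart <- max(nmax + 16, ceiling(abs(mx)) + 16)
  D <- complex(real = 0, imaginary = 0)
  Dv <- rep(D, nstart)
  for (k in seq(nstart - 1, 1)) {
    Dv[k] <- (k + 1) / mx - 1 / (Dv[k + 1] + (k + 1) / mx)
  }
  D <- Dv[n]
  ## Riccati-Bessel psi_n(x), chi_n(x) by upward recursion
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi0 <- sin(x); psi1 <- sin(x) / x - cos(x)
  chi0 <- cos(x); chi1 <- cos(x) / x + sin(x)
  psi[1] <- psi1; chi[1] <- chi1
  if (nmax >= 2) {
    pm1 <- psi0; p <- psi1; cm1 <- chi0; cc <- chi1
    for (k in 2:nmax) {
      pn <- (2 * k - 1) / x * p - pm1
      cn <- (2 * k - 1) / x * cc - cm1
      psi[k] <- pn; chi[k] <- cn
      pm1 <- p; p <- pn; cm1 <- cc; cc <- cn
    }
  }
  xi <- complex(real = psi, imaginary = -chi)
  psi_prev <- c(psi0, psi[-nmax])
  xi_prev <- complex(real = psi_prev, imaginary = -c(chi0, chi[-nmax]))
  ta <- D / m + n / x
  tb <- D * m + n / x
  a <- (ta * psi - psi_prev) / (ta * xi - xi_prev)
  b <- (tb * psi - psi_prev) / (tb * xi - xi_prev)
  list(n = n, a = a, b = b)
}

#' Optical properties of a nanoparticle calibration phantom
#'
#' Mie-theory scattering coefficient and asymmetry parameter of a monodisperse
#' sphere suspension, as used for the polystyrene nanoparticle calibration
#' series. `mu_s` is the product of the sphere number density and the Mie
#' scattering cross-section, so it is exactly linear in concentration.
#'
#' @param diameter_nm Sphere diameter, nm.
#' @param n_particle,n_medium Refractive indices of sphere and suspension
#'   medium (e.g. 1.59 for polystyrene, 1.33 for water).
#' @param wavelength_nm Vacuum wavelength, nm.
#' @param concentration Number density, spheres per mL.
#' @return List with `mu_s` (mm^-1), `g`, `csca_nm2` (scattering cross-section,
#'   nm^2) and `qsca` (scattering efficiency).
#' @export
mie_phantom_properties <- function(diameter_nm, n_particle, n_medium,
                                   wavelength_nm, concentration) {
  if (diameter_nm <= 0) stop("diameter must be > 0")
  if (wavelength_nm <= 0) stop("wavelength must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  r <- diameter_nm / 2
  x <- 2 * pi * r * n_medium / wavelength_nm
  m <- n_particle / n_medium
  co <- mie_coefficients(m, x)
  n <- co$n; a <- co$a; b <- co$b
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  s1 <- 0
  if (length(n) >= 2) {
    k <- n[-length(n)]
    s1 <- sum(k * (k + 2) / (k + 1) *
                Re(a[-length(a)] * Conj(a[-1]) + b[-length(b)] * Conj(b[-1])))
  }
  s2 <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- (4 / (x^2 * qsca)) * (s1 + s2)
  csca_nm2 <- qsca * pi * r^2
  ## spheres/mL -> spheres/mm^3 (x1e-3); nm^2 -> mm^2 (x1e-12)
  mu_s <- concentration * 1e-3 * csca_nm2 * 1e-12
  list(mu_s = mu_s, g = g, csca_nm2 = csca_nm2, qsca = qsca)
}

## ---- collection factors a(g), b(g, NA) ------------------------------------

## Henyey-Greenstein CDF in cos(theta): P(cos <= c)
hg_cdf <- function(c, g) {
  if (g < 1e-8) return((1 + c) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
}

#' Build the default collection-factor table
#'
#' The OCT forward model needs two scalar collection factors: `a(g)`, the
#' fraction of scattering events that deflect light outside the detection
#' acceptance (it scales the contribution of `mu_s` to the measured
#' attenuation and falls from 1 at g = 0 to 0 at g = 1), and `b(g, NA)`, the
#' fraction of coherence-gated scattered light that is backscattered into the
#' collection cone of the objective (it falls from 1.04e-4 at g = 0 to 0 at
#' g = 1 for NA = 0.075). Closed forms are not available for the instrument,
#' so the default table is derived from the Henyey--Greenstein phase function:
#' `a(g)` as the HG probability of deflection beyond the acceptance half-angle
#' `asin(NA)`, rescaled linearly so a(0) = 1 and a(1) = 0; `b(g, NA)` as the
#' HG probability of deflection into the backward cone of the same half-angle,
#' rescaled so b(0, 0.075) = 1.04e-4. The table is user-replaceable
#' (see [read_collection_table()]).
#'
#' @param na Numerical aperture of the collection optics.
#' @param n_grid Number of anisotropy nodes over `[0, 1]`.
#' @param b0 Anchor value for `b(0, na)`.
#' @return A `collection_factor_table`: data.frame with columns `g`, `a_g`,
#'   `b_g`, carrying `na` as an attribute.
#' @export
hg_collection_table <- function(na = 0.075, n_grid = 1001, b0 = 1.04e-4) {
  if (na <= 0 || na >= 1) stop("numerical aperture must lie in (0, 1)")
  theta_acc <- asin(na)
  c_acc <- cos(theta_acc)
  g_grid <- seq(0, 1, length.out = n_grid)
  ## raw HG integrals; at g = 1 all scattering is exactly forward
  a_raw <- vapply(g_grid, function(g) {
    if (g >= 1 - 1e-12) 0 else hg_cdf(c_acc, g)       # deflected out of the cone
  }, numeric(1))
  b_raw <- vapply(g_grid, function(g) {
    if (g >= 1 - 1e-12) 0 else hg_cdf(-c_acc, g)      # into the backward cone
  }, numeric(1))
  a_g <- (a_raw - a_raw[n_grid]) / (a_raw[1] - a_raw[n_grid])
  b_g <- b0 * b_raw / b_raw[1]
  out <- data.frame(g = g_grid, a_g = a_g, b_g = b_g)
  attr(out, "na") <- na
  class(out) <- c("collection_factor_table", "data.frame")
  out
}

validate_collection_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("g", "a_g", "b_g") %in% names(table)))
  if (is.unsorted(table$g, strictly = TRUE)) stop("g grid must be strictly increasing")
  if (any(diff(table$a_g) > 1e-12) || any(diff(table$b_g) > 1e-12))
    stop("a(g) and b(g) must be non-increasing in g")
  invisible(table)
}

#' Interpolate the collection factors at a given anisotropy
#'
#' @param g Anisotropy value(s) in `[0, 1]`.
#' @param table A collection-factor table (default [hg_collection_table()]).
#' @return List with vectors `a_g` and `b_g`.
#' @export
collection_factors <- function(g, table = hg_collection_table()) {
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    stop("g must lie in [0, 1]")
  a_g <- stats::approx(table$g, table$a_g, xout = g, rule = 2)$y
  b_g <- stats::approx(table$g, table$b_g, xout = g, rule = 2)$y
  list(a_g = a_g, b_g = b_g)
}

#' Read / write a collection-factor table as CSV
#'
#' CSV interchange format with header `g,a_g,b_g`, so a table computed
#' elsewhere (e.g. from an exact instrument model) can replace the built-in
#' Henyey--Greenstein default.
#'
#' @param path File path.
#' @param table Table to write.
#' @return `read_collection_table` returns a validated table.
#' @export
read_collection_table <- function(path) {
  out <- utils::read.csv(path)
  validate_collection_table(out)
  class(out) <- c("collection_factor_table", "data.frame")
  out
}

#' @rdname read_collection_table
#' @export
write_collection_table <- function(table, path) {
  utils::write.csv(table[, c("g", "a_g", "b_g")], path, row.names = FALSE)
  invisible(path)
}

## ---- forward model (mu, rho) <- (mu_s, g) ---------------------------------

#' Forward model: one-way OCT attenuation coefficient
#'
#' `mu = (a(g) mu_s + mu_a) G(NA)`. The confocal factor `G(NA)` is
#' approximately 1 for a low-NA system and defaults to 1.
#'
#' @param props An [optical_properties()] object (or list with `mu_a`, `mu_s`,
#'   `g`).
#' @param table Collection-factor table.
#' @param g_na Confocal factor `G(NA)`.
#' @return One-way attenuation coefficient, mm^-1.
#' @export
forward_attenuation <- function(props, table = hg_collection_table(), g_na = 1.0) {
  cf <- collection_factors(props$g, table)
  (cf$a_g * props$mu_s + props$mu_a) * g_na
}

#' Forward model: coherence-gated local reflectivity
#'
#' `rho = mu_s L_cg b(g, NA)`: the fraction of incident photons scattered
#' within one coherence-gate length, times the fraction of that scattered
#' light collected in backscatter.
#'
#' @param props An [optical_properties()] object.
#' @param l_cg Coherence-gate length, mm.
#' @param table Collection-factor table.
#' @return Local reflectivity, dimensionless.
#' @export
forward_reflectivity <- function(props, l_cg, table = hg_collection_table()) {
  if (l_cg <= 0) stop("coherence-gate length must be > 0")
  cf <- collection_factors(props$g, table)
  props$mu_s * l_cg * cf$b_g
}
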