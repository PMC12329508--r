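# Independent single-purpose Monte Carlo oracle for diffuse reflectance of a
# homogeneous box with absorbing boundaries and a collimated full-field top
# beam. Deliberately written as a separate code path from the package engine:
# continuous space (no voxel stepping), vectorised over photons, R's RNG.
mc_box_oracle <- function(mu_a, mu_s, g, box_mm, n_photons,
                          w_min = 1e-4, p_surv = 0.1) {
  mt <- mu_a + mu_s
  x <- stats::runif(n_photons, 0, box_mm[1])
  y <- stats::runif(n_photons, 0, box_mm[2])
  z <- rep(0, n_photons)
  ux <- rep(0, n_photons); uy <- rep(0, n_photons); uz <- rep(1, n_photons)
  W <- rep(1, n_photons)
  scattered <- rep(FALSE, n_photons)
  r_top <- 0; absorbed <- 0; lost_other <- 0
  alive <- rep(TRUE, n_photons)
  while (any(alive)) {
    n <- sum(alive)
    s <- -log(stats::runif(n)) / mt
    nx <- x[alive] + ux[alive] * s
    ny <- y[alive] + uy[alive] * s
    nz <- z[alive] + uz[alive] * s
    out <- nx < 0 | nx > box_mm[1] | ny < 0 | ny > box_mm[2] |
      nz < 0 | nz > box_mm[3]
    ## which face is crossed first along the segment
    esc_top <- rep(FALSE, n)
    if (any(out)) {
      io <- which(out)
      tx <- ifelse(ux[alive][io] > 0, (box_mm[1] - x[alive][io]) / ux[alive][io],
                   ifelse(ux[alive][io] < 0, -x[alive][io] / ux[alive][io], Inf))
      ty <- ifelse(uy[alive][io] > 0, (box_mm[2] - y[alive][io]) / uy[alive][io],
                   ifelse(uy[alive][io] < 0, -y[alive][io] / uy[alive][io], Inf))
      tz_top <- ifelse(uz[alive][io] < 0, -z[alive][io] / uz[alive][io], Inf)
      tz_bot <- ifelse(uz[alive][io] > 0, (box_mm[3] - z[alive][io]) / uz[alive][io], Inf)
      esc_top[io] <- tz_top < pmin(tx, pmin(ty, tz_bot))
    }
    ids <- which(alive)
    w_here <- W[ids]
    r_top <- r_top + sum(w_here[out & esc_top & scattered[ids]])
    lost_other <- lost_other +
      sum(w_here[out & (!esc_top | !scattered[ids])])
    keep <- ids[!out]
    alive[ids[out]] <- FALSE
    if (length(keep) == 0) break
    x[keep] <- nx[!out]; y[keep] <- ny[!out]; z[keep] <- nz[!out]
    ## absorb + scatter
    absorbed <- absorbed + sum(W[keep]) * mu_a / mt
    W[keep] <- W[keep] * mu_s / mt
    scattered[keep] <- TRUE
    m <- length(keep)
    ct <- if (g < 1e-8) stats::runif(m, -1, 1) else {
      f <- (1 - g^2) / (1 - g + 2 * g * stats::runif(m))
      pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
    }
    st <- sqrt(pmax(0, 1 - ct^2))
    phi <- stats::runif(m, 0, 2 * pi)
    cp <- cos(phi); sp <- sin(phi)
    u0x <- ux[keep]; u0y <- uy[keep]; u0z <- uz[keep]
    vert <- abs(u0z) > 0.99999
    den <- sqrt(pmax(1e-12, 1 - u0z^2))
    nux <- ifelse(vert, st * cp, st * (u0x * u0z * cp - u0y * sp) / den + u0x * ct)
    nuy <- ifelse(vert, st * sp, st * (u0y * u0z * cp + u0x * sp) / den + u0y * ct)
    nuz <- ifelse(vert, ct * sign(u0z), -den * st * cp + u0z * ct)
    nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
    ux[keep] <- nux / nrm; uy[keep] <- nuy / nrm; uz[keep] <- nuz / nrm
    ## roulette
    low <- keep[W[keep] < w_min]
    if (length(low)) {
      surv <- stats::runif(length(low)) <= p_surv
      W[low[surv]] <- W[low[surv]] / p_surv
      alive[low[!surv]] <- FALSE
    }
  }
  list(r_d = r_top / n_photons, absorbed = absorbed / n_photons)
}
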