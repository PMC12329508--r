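#' Summarise the fluence-rate distribution of one model layer
#'
#' Computes the mean, median, variance, 95th percentile, range, skewness and
#' kurtosis of the incident-normalised fluence rate over all voxels carrying
#' the requested label, plus a histogram over `log10(phi)` (zero-fluence
#' voxels are counted separately, not log-transformed). Quantiles use linear
#' interpolation between order statistics (type 7); skewness and kurtosis are
#' the standardised 3rd and 4th central moments, kurtosis non-excess
#' (normal = 3) with the excess value also reported.
#'
#' @param fluence A [run_simulation()] result.
#' @param model The [voxel_model()] the simulation ran on.
#' @param layer Label code (1 water, 2 superficial, 3 volumetric).
#' @param n_bins Histogram bins over `log10(phi)`.
#' @return A `layer_fluence_summary` list.
#' @export
summarize_layer <- function(fluence, model, layer, n_bins = 60) {
  sel <- model$labels == layer
  if (!any(sel)) stop(sprintf("layer %s not present in model", layer))
  phi <- fluence$phi[sel]
  n <- length(phi)
  m <- mean(phi)
  v <- stats::var(phi)
  sdv <- sqrt(v)
  z <- if (sdv > 0) (phi - m) / sdv else rep(0, n)
  skew <- mean(z^3)
  kurt <- mean(z^4)
  pos <- phi[phi > 0]
  hist <- NULL
  if (length(pos) > 0) {
    lp <- log10(pos)
    br <- seq(min(lp), max(lp) + 1e-12, length.out = n_bins + 1)
    if (diff(range(lp)) == 0) br <- c(lp[1] - 0.5, lp[1] + 0.5)
    h <- graphics::hist(lp, breaks = br, plot = FALSE)
    hist <- list(log10_breaks = h$breaks, counts = h$counts,
                 n_zero = n - length(pos))
  }
  structure(list(layer = layer, n_voxels = n,
                 mean = m, median = stats::median(phi), variance = v,
                 p95 = unname(stats::quantile(phi, 0.95, type = 7)),
                 range = diff(range(phi)),
                 skewness = skew, kurtosis = kurt,
                 kurtosis_excess = kurt - 3,
                 histogram = hist), class = "layer_fluence_summary")
}

#' Summary table over several layers
#'
#' @param fluence A [run_simulation()] result.
#' @param model The model simulated.
#' @param layers Label codes to summarise (default water/superficial/
#'   volumetric).
#' @return Data frame, one row per layer.
#' @export
layer_summary_table <- function(fluence, model, layers = c(1, 2, 3)) {
  layers <- layers[vapply(layers, function(l) any(model$labels == l), logical(1))]
  do.call(rbind, lapply(layers, function(l) {
    s <- summarize_layer(fluence, model, l)
    data.frame(layer = l, n_voxels = s$n_voxels, mean = s$mean,
               median = s$median, variance = s$variance, p95 = s$p95,
               range = s$range, skewness = s$skewness, kurtosis = s$kurtosis)
  }))
}

#' Interface fluence enhancement
#'
#' The 95th percentile of the fluence rate over skeleton voxels that are
#' 6-adjacent to a water voxel (the skeleton--water interface). With the
#' fluence already normalised to the incident irradiance, a value above 1
#' means the interface sees more light than arrives from the source --
#' the backscatter build-up that concentrates light at the surface.
#'
#' @param fluence A [run_simulation()] result.
#' @param model The model simulated.
#' @param percentile Percentile reported (default 95).
#' @return Enhancement factor (incident-normalised fluence percentile).
#' @export
interface_enhancement <- function(fluence, model, percentile = 95) {
  lab <- model$labels
  d <- dim(lab)
  skel <- lab == 2L | lab == 3L
  water <- lab == 1L
  if (!any(skel) || !any(water))
    stop("model must contain both skeleton and water labels")
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim = d)
    if (ax == 1) {
      if (by == 1) out[2:d[1], , ] <- a[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- a[2:d[1], , ]
    } else if (ax == 2) {
      if (by == 1) out[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
    }
    out
  }
  near_water <- shift(water, 1, 1) | shift(water, 1, -1) |
    shift(water, 2, 1) | shift(water, 2, -1) |
    shift(water, 3, 1) | shift(water, 3, -1)
  iface <- skel & near_water
  if (!any(iface)) stop("no skeleton-water interface voxels")
  unname(stats::quantile(fluence$phi[iface], percentile / 100, type = 7))
}
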