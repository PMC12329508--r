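#' Reference median optical properties of Turbinaria reniformis features
#'
#' Published median inherent optical properties of *Turbinaria reniformis*
#' skeletal features measured by OCT (per-sample medians aggregated per
#' feature, layer and depth zone): the superficial-layer scattering
#' coefficient of coenosteum grooves and the superficial-layer anisotropy of
#' coenosteum spines, for shallow and mesophotic colonies, among others.
#' Used as inputs to the worked percent-difference examples (e.g. mesophotic
#' grooves scatter ~34% more strongly than shallow ones; shallow spines are
#' ~5% more forward-scattering than mesophotic ones).
#'
#' @return Data frame with columns `feature`, `layer`, `depth_zone`,
#'   `metric`, `value`.
#' @export
reference_feature_medians <- function() {
  utils::read.csv(system.file("extdata", "turbinaria_feature_medians.csv",
                              package = "coraloptics"))
}
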