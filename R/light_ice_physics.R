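#' Attenuation parameters for the two-layer snow/ice light model
#'
#' Diffuse attenuation coefficients for under-ice irradiance modelling.
#' Transmitted photosynthetically active radiation (PAR) is attenuated
#' exponentially per layer, `E_Z = E_0 * exp(-K_d * Z)`, with a distinct
#' coefficient for snow, for the uppermost (most scattering) portion of the
#' ice, and for the remaining ice column.
#'
#' @param k_snow Diffuse attenuation coefficient of snow, m^-1.
#' @param k_ice_top Coefficient for the uppermost ice layer, m^-1.
#' @param ice_top_thickness Thickness of that uppermost layer, m.
#' @param k_ice_deep Coefficient for ice below the top layer, m^-1.
#'
#' @return An object of class `attenuation_params`.
#' @examples
#' attenuation_params()  # defaults: 20, 5 (top 10 cm), 1 m^-1
#' @export
attenuation_params <- function(k_snow = 20, k_ice_top = 5,
                               ice_top_thickness = 0.10, k_ice_deep = 1) {
  stopifnot(is.numeric(k_snow), is.numeric(k_ice_top),
            is.numeric(k_ice_deep), is.numeric(ice_top_thickness))
  if (k_snow <= 0 || k_ice_top <= 0 || k_ice_deep <= 0)
    stop("attenuation coefficients must be > 0")
  if (ice_top_thickness < 0)
    stop("ice_top_thickness must be >= 0")
  structure(list(k_snow = k_snow, k_ice_top = k_ice_top,
                 ice_top_thickness = ice_top_thickness,
                 k_ice_deep = k_ice_deep),
            class = "attenuation_params")
}

#' Fraction of surface PAR transmitted through snow and sea ice
#'
#' Applies the exponential attenuation law layerwise: snow over the full snow
#' depth, the top-ice coefficient over at most the top-layer thickness, and
#' the deep-ice coefficient over the remainder of the ice column. Ice thinner
#' than the top layer is attenuated with the top-layer coefficient only, so
#' the model is continuous in ice thickness.
#'
#' @param snow_depth Snow depth in metres (scalar or vector).
#' @param ice_thickness Ice thickness in metres (scalar or vector).
#' @param params An [attenuation_params()] object.
#'
#' @return Transmittance as a fraction in `[0, 1]`, independent of the
#'   surface irradiance.
#' @examples
#' transmittance(0.143, 0.92)  # ~0.015 (1.5% incoming PAR)
#' @export
transmittance <- function(snow_depth, ice_thickness,
                          params = attenuation_params()) {
  stopifnot(inherits(params, "attenuation_params"))
  if (any(snow_depth < 0) || any(ice_thickness < 0))
    stop("snow_depth and ice_thickness must be >= 0")
  top <- pmin(ice_thickness, params$ice_top_thickness)
  deep <- pmax(ice_thickness - params$ice_top_thickness, 0)
  exp(-params$k_snow * snow_depth) *
    exp(-params$k_ice_top * top) *
    exp(-params$k_ice_deep * deep)
}

#' Transmitted PAR at the ice-water interface
#'
#' @param surface_par Surface irradiance E_0, umol photons m^-2 s^-1.
#' @param transmittance Fraction of surface PAR transmitted (see
#'   [transmittance()]).
#' @return Transmitted irradiance E_Z in the same units as `surface_par`.
#' @examples
#' transmitted_par(640, 0.232)  # ~148 umol m^-2 s^-1
#' @export
transmitted_par <- function(surface_par, transmittance) {
  if (any(surface_par < 0)) stop("surface_par must be >= 0")
  surface_par * transmittance
}

#' Classify a site by light transmissivity
#'
#' Sites receiving less than 5% of incoming PAR at the ice-water interface
#' are classed as low light-transmissivity (LLT); above 5%, high (HLT).
#' Exactly 5% is assigned to LLT (the low class is defined by the strict
#' "< 5%" inequality).
#'
#' @param transmittance Fraction in `[0, 1]` (scalar or vector).
#' @param threshold Class boundary as a fraction; default 0.05.
#' @return Factor with levels `LLT`, `HLT`.
#' @export
classify_light <- function(transmittance, threshold = 0.05) {
  if (any(transmittance < 0) || any(transmittance > 1))
    stop("transmittance must lie in [0, 1]")
  factor(ifelse(transmittance > threshold, "HLT", "LLT"),
         levels = c("LLT", "HLT"))
}

#' Brine salinity of sea ice at thermal equilibrium
#'
#' Equilibrium salinity of the liquid brine inclusions as a function of ice
#' temperature, `S_b = 1000 / (1 - 54.11 / T)` with T in degrees Celsius.
#' Valid for -22.9 <= T < 0 degC; a warning is issued below that range.
#'
#' @param ice_temperature Ice temperature in degC, must be < 0.
#' @return Brine salinity in ppt.
#' @examples
#' brine_salinity(-2.1)  # 37.36 ppt
#' @export
brine_salinity <- function(ice_temperature) {
  if (any(ice_temperature >= 0))
    stop("ice_temperature must be < 0 degC (ice at thermal equilibrium)")
  if (any(ice_temperature < -22.9))
    warning("ice_temperature below -22.9 degC: outside the validity range of the brine-salinity relation")
  1000 / (1 - 54.11 / ice_temperature)
}

#' Brine volume fraction of sea ice
#'
#' Frankenstein-Garner relation between bulk salinity, ice temperature and
#' the relative brine volume: `V_b (permille) = S * (49.185 / |T| + 0.532)`,
#' returned as percent of ice volume. Valid for -22.9 <= T < 0 degC.
#'
#' @param bulk_salinity Bulk (melted-core) salinity in ppt, >= 0.
#' @param ice_temperature Ice temperature in degC, must be < 0.
#' @return Brine volume as percent of ice volume.
#' @examples
#' brine_volume(6.5, -2.1)  # 15.57%
#' @export
brine_volume <- function(bulk_salinity, ice_temperature) {
  if (any(bulk_salinity < 0)) stop("bulk_salinity must be >= 0")
  if (any(ice_temperature >= 0))
    stop("ice_temperature must be < 0 degC")
  if (any(ice_temperature < -22.9))
    warning("ice_temperature below -22.9 degC: outside the validity range of the brine-volume relation")
  bulk_salinity * (49.185 / abs(ice_temperature) + 0.532) / 10
}

#' Derive light and brine state for a table of sampling sites
#'
#' Batch companion to the scalar physics functions. Accepts a site table
#' with snow depth and ice thickness in centimetres (the convention of field
#' core logs) or metres, and appends transmittance, percent incoming PAR,
#' transmitted PAR, light class and, when ice temperature and bulk salinity
#' are present, brine salinity and brine volume.
#'
#' @param sites Data frame with columns `station_id`, `snow_depth`,
#'   `ice_thickness`, and optionally `surface_par`, `ice_temperature`,
#'   `bulk_salinity`.
#' @param depth_unit Unit of the snow/ice columns: `"cm"` (default) or `"m"`.
#' @param params An [attenuation_params()] object.
#' @return The input data frame with derived columns appended:
#'   `transmittance_fraction`, `light_pct` (percent incoming PAR, full
#'   precision), `transmitted_par`, `light_class`, `brine_salinity`,
#'   `brine_volume_pct`.
#' @export
derive_site_environment <- function(sites, depth_unit = c("cm", "m"),
                                    params = attenuation_params()) {
  depth_unit <- match.arg(depth_unit)
  req <- c("station_id", "snow_depth", "ice_thickness")
  miss <- setdiff(req, names(sites))
  if (length(miss))
    stop("site table is missing required columns: ", paste(miss, collapse = ", "))
  scale <- if (depth_unit == "cm") 0.01 else 1
  snow <- sites$snow_depth * scale
  ice <- sites$ice_thickness * scale
  tr <- transmittance(snow, ice, params)
  sites$transmittance_fraction <- tr
  sites$light_pct <- 100 * tr
  if (!is.null(sites$surface_par))
    sites$transmitted_par <- transmitted_par(sites$surface_par, tr)
  sites$light_class <- classify_light(tr)
  if (!is.null(sites$ice_temperature)) {
    sites$brine_salinity <- brine_salinity(sites$ice_temperature)
    if (!is.null(sites$bulk_salinity))
      sites$brine_volume_pct <-
        brine_volume(sites$bulk_salinity, sites$ice_temperature)
  }
  sites
}
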