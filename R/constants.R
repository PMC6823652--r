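#' Physical constants for freeze-drying calculations
#'
#' Bundles the handbook material properties closing the freezing and
#' primary-drying balances. All values are in the practical unit system used
#' throughout the package (cal, g, cm, s, Torr, K) and every one can be
#' overridden.
#'
#' @param dhs Heat of sublimation of ice (cal/g).
#' @param k_ice Thermal conductivity of the frozen layer (cal/(s cm K)).
#' @param hf Latent heat of fusion of ice (cal/g).
#' @param cp_liquid Specific heat of the liquid product (cal/(g K)).
#' @param cp_ice Specific heat of ice (cal/(g K)).
#' @param rho_ice Density of ice (g/cm^3).
#' @param vp_a Pre-exponential coefficient of the ice vapor-pressure
#'   correlation (Torr).
#' @param vp_b Exponential temperature coefficient of the ice vapor-pressure
#'   correlation (K).
#'
#' @details The sublimation-front vapor pressure is modeled as
#'   \eqn{P_{sub}(T) = a \exp(-b/T)} with \eqn{T} in kelvin, the correlation
#'   in standard use for primary-drying models; it reproduces the ice
#'   triple-point pressure (4.58 Torr at 273.16 K) within 1%.
#'
#' @return An object of class `lyo_constants`.
#' @export
#' @examples
#' lyo_constants()
lyo_constants <- function(dhs = 678, k_ice = 0.0059, hf = 79.7,
                          cp_liquid = 1.0, cp_ice = 0.503, rho_ice = 0.918,
                          vp_a = 2.698e10, vp_b = 6144.96) {
  vals <- c(dhs = dhs, k_ice = k_ice, hf = hf, cp_liquid = cp_liquid,
            cp_ice = cp_ice, rho_ice = rho_ice, vp_a = vp_a, vp_b = vp_b)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  structure(as.list(vals), class = "lyo_constants")
}

#' Equilibrium vapor pressure over ice
#'
#' @param t_k Temperature in kelvin (vectorized).
#' @param constants A [lyo_constants()] object supplying the correlation
#'   coefficients.
#' @return Vapor pressure in Torr.
#' @export
#' @examples
#' ice_vapor_pressure(273.15) # ~4.57 Torr, near the triple point
ice_vapor_pressure <- function(t_k, constants = lyo_constants()) {
  if (any(!is.finite(t_k)) || any(t_k <= 0))
    stop("temperature must be positive (kelvin)")
  if (any(t_k <= 150 | t_k >= 280))
    warning("ice vapor-pressure correlation evaluated outside 150-280 K")
  constants$vp_a * exp(-constants$vp_b / t_k)
}

# Inverse of the vapor-pressure correlation: temperature (K) at which ice has
# the given equilibrium pressure (Torr).
ice_vapor_temperature <- function(p_torr, constants = lyo_constants()) {
  if (any(!is.finite(p_torr)) || any(p_torr <= 0))
    stop("pressure must be positive (Torr)")
  constants$vp_b / log(constants$vp_a / p_torr)
}

# seconds per hour, used to carry cal/s coefficients into the hour-based
# time integration
.S_PER_H <- 3600
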