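#' Convert between the unit systems of freeze-drying practice
#'
#' The lyophilization literature mixes SI and practical units: heat-transfer
#' coefficients appear both as W/(m^2 K) and cal/(s K cm^2), pressures as Pa,
#' Torr and mTorr. This helper converts between the supported pairs; all
#' internal package computation uses the practical system (cal, g, cm, Torr,
#' h) and conversion happens only at input/output.
#'
#' Supported units (grouped by dimension):
#' pressure `"Torr"`, `"mTorr"`, `"Pa"`; inverse pressure `"1/Torr"`,
#' `"1/Pa"`; heat-transfer coefficient `"cal/s/K/cm2"`, `"W/m2/K"`;
#' pressure-slope coefficient `"cal/s/K/cm2/Torr"`, `"W/m2/K/Pa"`;
#' temperature `"degC"`, `"K"`; mass rate `"kg/h"`, `"g/h"`.
#'
#' @param value Numeric value(s) to convert.
#' @param from,to Unit names as above.
#' @return The converted value(s).
#' @export
#' @examples
#' convert_units(2.75e-4, "cal/s/K/cm2", "W/m2/K")  # 11.51
#' convert_units(0.46, "1/Torr", "1/Pa")            # 3.45e-3
convert_units <- function(value, from, to) {
  reg <- .unit_registry()
  for (u in c(from, to)) {
    if (!u %in% rownames(reg))
      stop("unsupported unit '", u, "'; supported: ",
           paste(rownames(reg), collapse = ", "))
  }
  if (reg[from, "dim"] != reg[to, "dim"])
    stop("cannot convert '", from, "' to '", to, "': different dimensions")
  # to canonical: canonical = value * scale + offset
  canonical <- value * reg[from, "scale"] + reg[from, "offset"]
  (canonical - reg[to, "offset"]) / reg[to, "scale"]
}

# unit registry: linear maps onto a canonical unit per dimension
# (pressure -> Torr, htc -> cal/s/K/cm2, temperature -> K, rate -> kg/h)
.unit_registry <- function() {
  torr_per_pa <- 1 / 133.322
  cal_scale <- 1 / 41840  # W/m2/K per cal/s/K/cm2: 4.184 J/cal / 1e-4 m2
  u <- rbind(
    "Torr"             = c(1, 1, 0),
    "mTorr"            = c(1, 1e-3, 0),
    "Pa"               = c(1, torr_per_pa, 0),
    "1/Torr"           = c(2, 1, 0),
    "1/Pa"             = c(2, 1 / torr_per_pa, 0),
    "cal/s/K/cm2"      = c(3, 1, 0),
    "W/m2/K"           = c(3, cal_scale, 0),
    "cal/s/K/cm2/Torr" = c(4, 1, 0),
    "W/m2/K/Pa"        = c(4, cal_scale / torr_per_pa, 0),
    "degC"             = c(5, 1, 273.15),
    "K"                = c(5, 1, 0),
    "kg/h"             = c(6, 1, 0),
    "g/h"              = c(6, 1e-3, 0)
  )
  colnames(u) <- c("dim", "scale", "offset")
  u
}
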