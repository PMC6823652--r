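#' Vial geometry
#'
#' Describes a lyophilization vial by its outer and inner diameters. The
#' shelf-contact (heat-transfer) area `av` is computed from the outer
#' diameter and the product cross-section (sublimation) area `ap` from the
#' inner diameter, the convention of the vial heat-transfer literature.
#'
#' @param outer_diameter_mm Outer diameter (mm).
#' @param inner_diameter_mm Inner diameter (mm).
#' @param name Optional label.
#' @return An object of class `vial_geometry` with areas `av`, `ap` in cm^2.
#' @export
#' @examples
#' vial_geometry(22, 20, name = "Schott 6R")
vial_geometry <- function(outer_diameter_mm, inner_diameter_mm, name = NULL) {
  if (!is.finite(outer_diameter_mm) || !is.finite(inner_diameter_mm))
    stop("diameters must be finite")
  if (inner_diameter_mm <= 0 || inner_diameter_mm > outer_diameter_mm)
    stop("need 0 < inner_diameter <= outer_diameter")
  structure(list(
    outer_diameter_mm = outer_diameter_mm,
    inner_diameter_mm = inner_diameter_mm,
    av = pi * (outer_diameter_mm / 20)^2,  # mm diameter -> cm radius
    ap = pi * (inner_diameter_mm / 20)^2,
    name = name
  ), class = "vial_geometry")
}

#' @export
print.vial_geometry <- function(x, ...) {
  cat(sprintf("Vial%s: OD %.1f mm, ID %.1f mm (Av = %.3f cm^2, Ap = %.3f cm^2)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$outer_diameter_mm, x$inner_diameter_mm, x$av, x$ap))
  invisible(x)
}

#' Formulation properties
#'
#' Solution composition, densities, critical product temperature and the
#' dried-cake resistance coefficients of the formulation,
#' \eqn{R_p = R_0 + A_1 L_{ck} / (1 + A_2 L_{ck})}.
#'
#' @param csolid Solute mass concentration (g/mL).
#' @param r0 Cake-resistance offset (cm^2 h Torr/g).
#' @param a1 Cake-resistance slope (cm h Torr/g).
#' @param a2 Cake-resistance saturation coefficient (1/cm); 0 gives linear
#'   growth of resistance with cake length.
#' @param t_pr_max Critical/target product temperature (degC), the maximum
#'   allowable vial-bottom temperature during primary drying.
#' @param rho_solution Solution density (g/cm^3).
#' @param rho_solute Solute (true) density (g/cm^3).
#' @param rho_ice Ice density (g/cm^3).
#' @param name Optional label.
#' @return An object of class `lyo_formulation`.
#' @export
#' @examples
#' formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0, t_pr_max = -5,
#'             rho_solute = 1.52, name = "5% mannitol")
formulation <- function(csolid, r0, a1 = 0, a2 = 0, t_pr_max = -5,
                        rho_solution = 1.0, rho_solute = 1.52,
                        rho_ice = 0.918, name = NULL) {
  if (r0 <= 0) stop("r0 must be > 0")
  if (a1 < 0 || a2 < 0) stop("a1 and a2 must be >= 0")
  if (csolid < 0 || csolid >= rho_solution)
    stop("need 0 <= csolid < rho_solution")
  if (rho_ice >= rho_solution)
    warning("rho_ice >= rho_solution is unusual for aqueous formulations")
  structure(list(csolid = csolid, r0 = r0, a1 = a1, a2 = a2,
                 t_pr_max = t_pr_max, rho_solution = rho_solution,
                 rho_solute = rho_solute, rho_ice = rho_ice, name = name),
            class = "lyo_formulation")
}

#' Vial heat-transfer coefficient model
#'
#' Pressure-dependent vial heat-transfer coefficient
#' \eqn{K_v = K_c + K_p P_{ch} / (1 + K_D P_{ch})}, or a fixed value. The
#' pressure dependence arises from gas conduction in the gap between vial
#' bottom and shelf; `kc` collects the contact-conduction and radiation
#' contributions.
#'
#' @param kc Pressure-independent coefficient (cal/(s K cm^2)).
#' @param kp Gas-conduction coefficient (cal/(s K cm^2 Torr)).
#' @param kd Saturation coefficient (1/Torr).
#' @param fixed_kv Alternatively, a single fixed Kv (cal/(s K cm^2));
#'   mutually exclusive with `kc`/`kp`/`kd`.
#' @param name Optional label.
#' @return An object of class `heat_transfer_model`.
#' @export
#' @examples
#' htm <- heat_transfer_model(kc = 2.75e-4, kp = 8.93e-4, kd = 0.46)
#' kv_of_pressure(htm, 0.3)
heat_transfer_model <- function(kc = NULL, kp = NULL, kd = NULL,
                                fixed_kv = NULL, name = NULL) {
  has_curve <- !is.null(kc) || !is.null(kp) || !is.null(kd)
  if (!is.null(fixed_kv) && has_curve)
    stop("give either (kc, kp, kd) or fixed_kv, not both")
  if (!is.null(fixed_kv)) {
    if (fixed_kv <= 0) stop("fixed_kv must be > 0")
    out <- list(fixed_kv = fixed_kv, name = name)
  } else {
    if (is.null(kc) || is.null(kp) || is.null(kd))
      stop("kc, kp and kd must all be supplied")
    if (kc < 0 || kp < 0 || kd < 0) stop("kc, kp, kd must be >= 0")
    out <- list(kc = kc, kp = kp, kd = kd, name = name)
  }
  structure(out, class = "heat_transfer_model")
}

#' Evaluate the vial heat-transfer coefficient at a chamber pressure
#'
#' @param model A [heat_transfer_model()].
#' @param pch Chamber pressure (Torr), vectorized.
#' @return Kv in cal/(s K cm^2).
#' @export
kv_of_pressure <- function(model, pch) {
  stopifnot(inherits(model, "heat_transfer_model"))
  if (any(!is.finite(pch)) || any(pch < 0))
    stop("chamber pressure must be >= 0 Torr")
  if (!is.null(model$fixed_kv)) return(rep(model$fixed_kv, length(pch)))
  model$kc + model$kp * pch / (1 + model$kd * pch)
}

#' Dried-cake resistance at a given cake length
#'
#' @param form A [formulation()].
#' @param lck Cake (dried-layer) length (cm), vectorized.
#' @return Area-normalized product resistance (cm^2 h Torr/g).
#' @export
#' @examples
#' mann <- formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0)
#' rp_of_cake_length(mann, c(0, 0.35))
rp_of_cake_length <- function(form, lck) {
  stopifnot(inherits(form, "lyo_formulation"))
  if (any(!is.finite(lck)) || any(lck < 0))
    stop("cake length must be >= 0 cm")
  form$r0 + form$a1 * lck / (1 + form$a2 * lck)
}

#' Initial frozen product length
#'
#' Height of the frozen product in the vial after freezing, accounting for
#' the density change from solution to ice:
#' \deqn{L_{pr,0} = \frac{V_{fill}}{A_p \rho_{ice}}
#'   \left(\rho_{solution} - \frac{c_{solid}(\rho_{solution} -
#'   \rho_{ice})}{\rho_{solute}}\right)}
#'
#' @param vfill Fill volume (mL).
#' @param form A [formulation()].
#' @param ap Product cross-section area (cm^2).
#' @return Initial frozen length (cm).
#' @export
initial_frozen_length <- function(vfill, form, ap) {
  stopifnot(inherits(form, "lyo_formulation"))
  if (!is.finite(vfill) || vfill <= 0) stop("fill volume must be > 0 mL")
  if (!is.finite(ap) || ap <= 0) stop("product area must be > 0 cm^2")
  vfill / (ap * form$rho_ice) *
    (form$rho_solution -
       form$csolid * (form$rho_solution - form$rho_ice) / form$rho_solute)
}

#' Equipment capability line
#'
#' Maximum total sublimation rate the freeze-dryer sustains at a chamber
#' pressure, modeled as the line \eqn{\dot m_{eq\,cap} = a + b P_{ch}}
#' (choked duct flow / condenser limit). The coefficients come from choked
#' flow tests, minimum controllable pressure tests or CFD and are inputs
#' here.
#'
#' @param a Rate intercept (kg/h).
#' @param b Rate slope (kg/(h Torr)).
#' @param disabled If `TRUE`, the dryer is treated as unlimited (the
#'   capability rate is `Inf` everywhere).
#' @return An object of class `equipment_capability`.
#' @export
equipment_capability <- function(a = 0, b = 0, disabled = FALSE) {
  structure(list(a = a, b = b, disabled = isTRUE(disabled)),
            class = "equipment_capability")
}

#' Evaluate the equipment capability rate
#'
#' @param cap An [equipment_capability()].
#' @param pch Chamber pressure (Torr), vectorized.
#' @return Maximum total sublimation rate (kg/h); `Inf` when disabled.
#' @export
equipment_capability_rate <- function(cap, pch) {
  stopifnot(inherits(cap, "equipment_capability"))
  if (any(!is.finite(pch)) || any(pch < 0))
    stop("chamber pressure must be >= 0 Torr")
  if (cap$disabled) return(rep(Inf, length(pch)))
  rate <- cap$a + cap$b * pch
  if (any(rate < 0))
    stop("equipment capability line is negative at the supplied pressure")
  rate
}
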