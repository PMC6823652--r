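#' Primary-drying configuration
#'
#' Bundles everything a primary-drying simulation needs: vial geometry,
#' formulation, vial heat-transfer model, physical constants, fill and load,
#' and the shelf-temperature and chamber-pressure schedules.
#'
#' @param vial A [vial_geometry()].
#' @param form A [formulation()].
#' @param htm A [heat_transfer_model()].
#' @param vfill Fill volume per vial (mL).
#' @param shelf Shelf-temperature schedule (degC); a number means constant.
#' @param pressure Chamber-pressure schedule (Torr); a number means constant.
#' @param n_vials Number of vials in the batch (all treated as identical
#'   center vials).
#' @param dt Time step (h); default 0.05 h (3 min).
#' @param constants A [lyo_constants()] object.
#' @return An object of class `drying_config`.
#' @export
#' @examples
#' cfg <- drying_config(
#'   vial = vial_geometry(22, 20),
#'   form = formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0),
#'   htm = heat_transfer_model(fixed_kv = 5.1e-4),
#'   vfill = 2, shelf = -5, pressure = 0.3)
drying_config <- function(vial, form, htm, vfill, shelf, pressure,
                          n_vials = 1L, dt = 0.05,
                          constants = lyo_constants()) {
  stopifnot(inherits(vial, "vial_geometry"), inherits(form, "lyo_formulation"),
            inherits(htm, "heat_transfer_model"),
            inherits(constants, "lyo_constants"))
  if (dt <= 0) stop("dt must be > 0")
  if (n_vials < 1) stop("n_vials must be >= 1")
  if (vfill <= 0) stop("vfill must be > 0")
  structure(list(vial = vial, form = form, htm = htm, vfill = vfill,
                 shelf = as_schedule(shelf), pressure = as_schedule(pressure),
                 n_vials = as.integer(n_vials), dt = dt,
                 constants = constants),
            class = "drying_config")
}

# ---- internal quasi-steady solvers -----------------------------------------
# All work in practical units: cal, g, cm, Torr, h; temperatures in degC
# except inside the vapor-pressure correlation.

# Free solve: given shelf temperature, find the front temperature balancing
# heat supply against sublimation demand. Returns the full state.
qs_solve_free <- function(tsh, pch, lck, lpr0, kv, geom, form, const) {
  rp <- rp_of_cake_length(form, lck)
  lpr <- lpr0 - lck
  kv_h <- kv * .S_PER_H
  kice_h <- const$k_ice * .S_PER_H

  # no-sublimation fixed point: product equilibrates with the shelf
  p_eq <- const$vp_a * exp(-const$vp_b / (tsh + 273.15))
  if (p_eq <= pch) {
    return(list(t_sub = tsh, t_bot = tsh, p_sub = p_eq, flux = 0, q_dot = 0))
  }

  psub_of <- function(t_sub) const$vp_a * exp(-const$vp_b / (t_sub + 273.15))
  flux_of <- function(t_sub) (psub_of(t_sub) - pch) / rp     # g/(cm^2 h)
  # residual between heat supplied through the vial and heat demanded by
  # sublimation, as a function of the front temperature
  resid <- function(t_sub) {
    fl <- flux_of(t_sub)
    q <- fl * const$dhs * geom$ap                             # cal/h
    t_bot <- t_sub + q * lpr / (geom$ap * kice_h)
    (tsh - t_bot) * kv_h * geom$av - q
  }
  lo <- tsh - 200
  hi <- tsh
  root <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  fl <- flux_of(root)
  q <- fl * const$dhs * geom$ap
  t_bot <- root + q * lpr / (geom$ap * kice_h)
  if (fl < 0) { # numerically tiny negative: clamp at the fixed point
    fl <- 0; q <- 0; t_bot <- tsh; root <- tsh
  }
  list(t_sub = root, t_bot = t_bot, p_sub = psub_of(root), flux = fl,
       q_dot = q)
}

# Pinned solve: vial-bottom temperature fixed at t_bot (e.g. the critical
# product temperature); the frozen-layer conduction and cake vapor-transport
# legs alone determine the front state. The vial area cancels.
qs_solve_pinned <- function(t_bot, pch, lck, lpr0, form, const) {
  rp <- rp_of_cake_length(form, lck)
  lpr <- lpr0 - lck
  kice_h <- const$k_ice * .S_PER_H
  psub_of <- function(t_sub) const$vp_a * exp(-const$vp_b / (t_sub + 273.15))

  if (psub_of(t_bot) <= pch) {
    return(list(t_sub = t_bot, p_sub = psub_of(t_bot), flux = 0))
  }
  if (lpr <= 1e-9) { # vanishing frozen layer: zero conduction resistance
    return(list(t_sub = t_bot, p_sub = psub_of(t_bot),
                flux = (psub_of(t_bot) - pch) / rp))
  }
  resid <- function(t_sub) {
    (t_bot - t_sub) * kice_h / lpr -
      (psub_of(t_sub) - pch) * const$dhs / rp
  }
  root <- stats::uniroot(resid, c(t_bot - 150, t_bot), tol = 1e-12)$root
  fl <- (psub_of(root) - pch) / rp
  list(t_sub = root, p_sub = psub_of(root), flux = max(fl, 0))
}

# Shelf temperature required to drive a given per-area flux with the vial
# bottom at t_bot.
tsh_required_for <- function(flux, t_bot, kv, geom, const) {
  q <- flux * const$dhs * geom$ap
  t_bot + q / (kv * .S_PER_H * geom$av)
}

#' Solve the quasi-steady heat/mass balance at one instant
#'
#' Solves the coupled balance of shelf-to-vial heat transfer, conduction
#' through the frozen layer, and vapor transport through the dried cake,
#' \deqn{\dot Q = (T_{sh} - T_{bot}) K_v A_v
#'             = (T_{bot} - T_{sub}) A_p k_{ice} / L_{pr}
#'             = (P_{sub} - P_{ch}) A_p \Delta H_s / R_p,}
#' for the sublimation-front temperature, vial-bottom temperature and
#' sublimation mass flux at a given cake length.
#'
#' @param lck Current cake (dried) length (cm).
#' @param lpr0 Initial frozen product length (cm).
#' @param tsh Shelf temperature (degC).
#' @param pch Chamber pressure (Torr).
#' @param config A [drying_config()].
#' @return A list of class `quasi_steady_state` with `t_sub`, `t_bot` (degC),
#'   `p_sub` (Torr), `flux` (g/(cm^2 h)) and `q_dot` (cal/h). The flux is
#'   floored at zero when the front vapor pressure cannot exceed the chamber
#'   pressure.
#' @export
quasi_steady_solve <- function(lck, lpr0, tsh, pch, config) {
  stopifnot(inherits(config, "drying_config"))
  if (lck < 0 || lck > lpr0 + 1e-12) stop("need 0 <= lck <= lpr0")
  kv <- kv_of_pressure(config$htm, pch)
  lpr <- lpr0 - lck
  if (lpr <= 1e-9) {
    # degenerate frozen layer: bottom and front coincide; balance the vial
    # heat-supply leg directly against sublimation
    st <- qs_solve_free(tsh, pch, lck, lck + 1e-9, kv, config$vial,
                        config$form, config$constants)
  } else {
    st <- qs_solve_free(tsh, pch, lck, lpr0, kv, config$vial, config$form,
                        config$constants)
  }
  structure(st, class = "quasi_steady_state")
}

# shared bookkeeping for drying time series
new_drying_series <- function(rec, lpr0, drying_time) {
  structure(list(profile = rec, lpr0 = lpr0, drying_time = drying_time,
                 max_t_bot = max(rec$t_bot), mean_t_bot = mean(rec$t_bot)),
            class = "drying_series")
}

#' @export
print.drying_series <- function(x, ...) {
  cat(sprintf(paste0("Primary drying: %.3f h (Lpr0 = %.4f cm, ",
                     "max Tbot = %.2f degC, mean Tbot = %.2f degC)\n"),
              x$drying_time, x$lpr0, x$max_t_bot, x$mean_t_bot))
  invisible(x)
}

#' Simulate primary drying by time stepping
#'
#' Advances the sublimation front through the frozen product: at each time
#' step the schedules are evaluated, the quasi-steady balance is solved, and
#' the cake grows by `flux * dt / rho_ice`. The run ends when the cake
#' length reaches the initial frozen length, with the final partial step
#' linearly interpolated.
#'
#' @param config A [drying_config()].
#' @param t_max Safety cap on simulated time (h).
#' @return A `drying_series`: list with per-step `profile` data frame
#'   (t, lck, t_sub, t_bot, p_sub, flux, tsh, pch), `lpr0`, `drying_time`
#'   (h), `max_t_bot` and `mean_t_bot` (degC).
#' @export
#' @examples
#' cfg <- drying_config(vial_geometry(22, 20),
#'                      formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0),
#'                      heat_transfer_model(fixed_kv = 5.1e-4),
#'                      vfill = 2, shelf = -5, pressure = 0.3)
#' simulate_primary_drying(cfg)$drying_time
simulate_primary_drying <- function(config, t_max = 2000) {
  stopifnot(inherits(config, "drying_config"))
  lpr0 <- initial_frozen_length(config$vfill, config$form, config$vial$ap)
  rho_ice <- config$form$rho_ice
  dt <- config$dt

  t <- 0; lck <- 0
  rows <- list()
  i <- 0L
  drying_time <- NA_real_
  while (t < t_max) {
    tsh <- schedule_value(config$shelf, t)
    pch <- schedule_value(config$pressure, t)
    st <- quasi_steady_solve(lck, lpr0, tsh, pch, config)
    i <- i + 1L
    rows[[i]] <- c(t = t, lck = lck, t_sub = st$t_sub, t_bot = st$t_bot,
                   p_sub = st$p_sub, flux = st$flux, tsh = tsh, pch = pch)
    if (i == 1L && st$flux <= 0)
      stop("no sublimation possible at the initial setpoints ",
           "(front vapor pressure does not exceed chamber pressure)")
    dlck <- st$flux * dt / rho_ice
    if (lck + dlck >= lpr0) {
      frac <- if (dlck > 0) (lpr0 - lck) / dlck else 0
      drying_time <- t + frac * dt
      break
    }
    lck <- lck + dlck
    t <- t + dt
  }
  if (is.na(drying_time))
    stop("drying did not complete within t_max = ", t_max, " h")
  rec <- as.data.frame(do.call(rbind, rows))
  new_drying_series(rec, lpr0, drying_time)
}

#' Simulate primary drying by product-length divisions
#'
#' The classical alternative stepping scheme: the frozen product length is
#' divided into `n_divisions` equal cake increments; within each increment
#' the sublimation flux is held at its start-of-segment value and the time
#' to dry the increment is `dlck * rho_ice / flux`. Coarse divisions
#' under-resolve the falling flux and underestimate the drying time;
#' the scheme converges to the time-stepping result as `n_divisions` grows.
#'
#' @param config A [drying_config()]. Schedules are evaluated at the running
#'   segment-start times.
#' @param n_divisions Number of equal cake-length divisions (>= 1).
#' @return A `drying_series`, as [simulate_primary_drying()].
#' @export
simulate_primary_drying_by_divisions <- function(config, n_divisions) {
  stopifnot(inherits(config, "drying_config"))
  if (n_divisions < 1) stop("n_divisions must be >= 1")
  lpr0 <- initial_frozen_length(config$vfill, config$form, config$vial$ap)
  rho_ice <- config$form$rho_ice
  dl <- lpr0 / n_divisions

  t <- 0
  rows <- list()
  for (k in seq_len(n_divisions)) {
    lck <- (k - 1L) * dl
    tsh <- schedule_value(config$shelf, t)
    pch <- schedule_value(config$pressure, t)
    st <- quasi_steady_solve(lck, lpr0, tsh, pch, config)
    if (st$flux <= 0)
      stop("zero sublimation flux at segment ", k,
           ": cannot advance the front")
    rows[[k]] <- c(t = t, lck = lck, t_sub = st$t_sub, t_bot = st$t_bot,
                   p_sub = st$p_sub, flux = st$flux, tsh = tsh, pch = pch)
    t <- t + dl * rho_ice / st$flux
  }
  rec <- as.data.frame(do.call(rbind, rows))
  new_drying_series(rec, lpr0, drying_time = t)
}
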