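#' Constraints for the per-time-step cycle optimizer
#'
#' @param t_pr_max Maximum allowable vial-bottom product temperature (degC).
#' @param tsh_min,tsh_max Shelf-temperature bounds (degC).
#' @param pch_min,pch_max Chamber-pressure bounds (Torr).
#' @param cap An [equipment_capability()] limiting the total batch
#'   sublimation rate; disabled by default.
#' @param mode `"both"` optimizes chamber pressure and shelf temperature;
#'   `"pch-only"` optimizes pressure with the shelf on its schedule;
#'   `"tsh-only"` optimizes shelf temperature with pressure on its schedule.
#' @param control_interval Re-optimization interval (h); default 0.05 h
#'   (3 min).
#' @return An object of class `optimizer_constraints`.
#' @export
optimizer_constraints <- function(t_pr_max = -5, tsh_min = -60,
                                  tsh_max = 120, pch_min = 0.05,
                                  pch_max = 1,
                                  cap = equipment_capability(disabled = TRUE),
                                  mode = c("both", "pch-only", "tsh-only"),
                                  control_interval = 0.05) {
  mode <- match.arg(mode)
  if (tsh_min >= tsh_max) stop("need tsh_min < tsh_max")
  if (pch_min >= pch_max) stop("need pch_min < pch_max")
  if (!is.finite(t_pr_max)) stop("t_pr_max must be finite")
  if (control_interval <= 0) stop("control interval must be > 0")
  structure(list(t_pr_max = t_pr_max, tsh_min = tsh_min, tsh_max = tsh_max,
                 pch_min = pch_min, pch_max = pch_max, cap = cap,
                 mode = mode, control_interval = control_interval),
            class = "optimizer_constraints")
}

# Evaluate the best admissible (flux, tsh, binding tag) at one chamber
# pressure: shelf temperature is the lower of its ceiling and the value
# pinning the bottom at t_pr_max, then reduced further if the equipment
# capability binds.
.step_at_pch <- function(pch, lck, lpr0, config, cons, tsh_fixed = NULL) {
  const <- config$constants
  geom <- config$vial
  form <- config$form
  kv <- kv_of_pressure(config$htm, pch)
  rp <- rp_of_cake_length(form, lck)
  lpr <- lpr0 - lck
  kice_h <- const$k_ice * .S_PER_H
  cap_rate <- equipment_capability_rate(cons$cap, pch)      # kg/h total
  cap_flux <- cap_rate * 1000 / (config$n_vials * geom$ap)  # g/(cm^2 h)

  if (is.null(tsh_fixed)) {
    pin <- qs_solve_pinned(cons$t_pr_max, pch, lck, lpr0, form, const)
    tsh_req <- tsh_required_for(pin$flux, cons$t_pr_max, kv, geom, const)
    if (tsh_req <= cons$tsh_max && tsh_req >= cons$tsh_min) {
      tsh <- tsh_req; flux <- pin$flux
      st <- list(t_sub = pin$t_sub, t_bot = cons$t_pr_max, p_sub = pin$p_sub,
                 flux = flux, q_dot = flux * const$dhs * geom$ap)
      tag <- "Tpr-max"
    } else {
      tsh <- if (tsh_req > cons$tsh_max) cons$tsh_max else cons$tsh_min
      st <- qs_solve_free(tsh, pch, lck, lpr0, kv, geom, form, const)
      flux <- st$flux
      tag <- if (tsh_req > cons$tsh_max) "Tsh-max" else "Tsh-min"
    }
  } else {
    tsh <- tsh_fixed
    st <- qs_solve_free(tsh, pch, lck, lpr0, kv, geom, form, const)
    flux <- st$flux
    tag <- "schedule"
    if (st$t_bot > cons$t_pr_max + 1e-9)
      return(list(feasible = FALSE, flux = -Inf, tsh = tsh, state = st,
                  tag = "Tpr-max-violated"))
  }

  if (is.finite(cap_flux) && flux > cap_flux) {
    # hold the batch at the capability rate: back out the state at cap flux
    flux <- cap_flux
    p_sub <- pch + flux * rp
    t_sub <- ice_vapor_temperature(p_sub, const) - 273.15
    t_bot <- t_sub + flux * const$dhs * lpr / kice_h
    tsh <- tsh_required_for(flux, t_bot, kv, geom, const)
    if (!is.null(tsh_fixed) && t_bot > cons$t_pr_max + 1e-9)
      return(list(feasible = FALSE, flux = -Inf, tsh = tsh,
                  state = NULL, tag = "Tpr-max-violated"))
    st <- list(t_sub = t_sub, t_bot = t_bot, p_sub = p_sub, flux = flux,
               q_dot = flux * const$dhs * geom$ap)
    tag <- "equipment"
    if (tsh < cons$tsh_min) {
      tsh <- cons$tsh_min
      st <- qs_solve_free(tsh, pch, lck, lpr0, kv, geom, form, const)
      flux <- st$flux
      tag <- "Tsh-min"
    }
  }
  list(feasible = TRUE, flux = flux, tsh = tsh, state = st, tag = tag)
}

#' Optimize the setpoints for one time step
#'
#' Finds the chamber pressure and shelf temperature maximizing the
#' instantaneous sublimation flux subject to the product-temperature limit,
#' the shelf-temperature and pressure bounds, and the equipment capability.
#' On the product-limited branch the shelf temperature is the value pinning
#' the vial bottom exactly at `t_pr_max`; where that exceeds the shelf
#' ceiling, the ceiling applies. The pressure search combines a coarse
#' log-spaced scan with golden-section refinement; ties resolve to the lower
#' pressure.
#'
#' @param lck Current cake length (cm).
#' @param lpr0 Initial frozen length (cm).
#' @param config A [drying_config()].
#' @param cons An [optimizer_constraints()].
#' @param t Current time (h), used to read the fixed schedule in single-
#'   variable modes.
#' @return List `(pch, tsh, state, tag)` where `state` is the quasi-steady
#'   state at the optimum and `tag` names the binding constraint.
#' @export
optimize_step <- function(lck, lpr0, config, cons, t = 0) {
  stopifnot(inherits(config, "drying_config"),
            inherits(cons, "optimizer_constraints"))
  if (lck >= lpr0) stop("need lck < lpr0")

  if (cons$mode == "tsh-only") {
    pch <- schedule_value(config$pressure, t)
    cand <- .step_at_pch(pch, lck, lpr0, config, cons)
    if (!cand$feasible || cand$flux <= 0)
      stop("no feasible shelf temperature at the scheduled pressure")
    return(list(pch = pch, tsh = cand$tsh, state = cand$state,
                tag = cand$tag))
  }

  tsh_fixed <- if (cons$mode == "pch-only")
    schedule_value(config$shelf, t) else NULL

  eval_pch <- function(p) .step_at_pch(p, lck, lpr0, config, cons,
                                       tsh_fixed = tsh_fixed)
  grid <- exp(seq(log(cons$pch_min), log(cons$pch_max), length.out = 41))
  fl <- vapply(grid, function(p) eval_pch(p)$flux, numeric(1))

  if (all(!is.finite(fl) | fl <= 0)) {
    if (!is.null(tsh_fixed))
      stop("no feasible chamber pressure: the product-temperature limit is ",
           "violated across [pch_min, pch_max] at the scheduled shelf ",
           "temperature")
    stop("no feasible setpoint within the constraint box")
  }
  i <- which.max(fl)  # first maximum -> lower pressure on plateaus
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  # golden-section on log pressure inside the bracketing interval
  opt <- stats::optimize(function(lp) {
    v <- eval_pch(exp(lp))$flux
    if (!is.finite(v)) v <- -1e30
    -v
  }, c(log(lo), log(hi)), tol = 1e-8)
  pch_opt <- exp(opt$minimum)
  # ties (flat flux plateaus) resolve to the lower pressure: cheaper vacuum
  cand <- sort(c(pch_opt, grid[i]))
  f1 <- eval_pch(cand[1])$flux
  f2 <- eval_pch(cand[2])$flux
  pch_opt <- if (f1 >= f2 * (1 - 1e-10)) cand[1] else cand[2]
  best <- eval_pch(pch_opt)
  list(pch = pch_opt, tsh = best$tsh, state = best$state, tag = best$tag)
}

#' Optimize a full primary-drying cycle
#'
#' Repeats [optimize_step()] every control interval and advances the
#' sublimation front with the optimal flux, producing variable
#' chamber-pressure and/or shelf-temperature profiles and the minimized
#' drying time.
#'
#' @param config A [drying_config()]; in single-variable modes the fixed
#'   variable follows the corresponding schedule in `config`.
#' @param cons An [optimizer_constraints()].
#' @return An object of class `optimized_cycle` (extends `drying_series`):
#'   `profile` gains columns `pch_opt`, `tsh_opt` and `binding`.
#' @export
#' @examples
#' \donttest{
#' cfg <- drying_config(vial_geometry(22, 20),
#'                      formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0),
#'                      heat_transfer_model(kc = 2.75e-4, kp = 8.93e-4,
#'                                          kd = 0.46),
#'                      vfill = 2, shelf = 30, pressure = 0.15,
#'                      n_vials = 398)
#' res <- optimize_cycle(cfg, optimizer_constraints(t_pr_max = -5))
#' res$drying_time
#' }
optimize_cycle <- function(config, cons) {
  stopifnot(inherits(config, "drying_config"),
            inherits(cons, "optimizer_constraints"))
  lpr0 <- initial_frozen_length(config$vfill, config$form, config$vial$ap)
  dt <- cons$control_interval
  rho_ice <- config$form$rho_ice

  t <- 0; lck <- 0
  rows <- list(); tags <- character(); i <- 0L
  drying_time <- NA_real_
  repeat {
    opt <- optimize_step(lck, lpr0, config, cons, t = t)
    st <- opt$state
    i <- i + 1L
    rows[[i]] <- c(t = t, lck = lck, t_sub = st$t_sub, t_bot = st$t_bot,
                   p_sub = st$p_sub, flux = st$flux, tsh = opt$tsh,
                   pch = opt$pch)
    tags[i] <- opt$tag
    dlck <- st$flux * dt / rho_ice
    if (dlck <= 0)
      stop("optimizer reached zero flux before drying completed")
    if (lck + dlck >= lpr0) {
      drying_time <- t + (lpr0 - lck) / dlck * dt
      break
    }
    lck <- lck + dlck
    t <- t + dt
  }
  rec <- as.data.frame(do.call(rbind, rows))
  rec$pch_opt <- rec$pch
  rec$tsh_opt <- rec$tsh
  rec$binding <- tags
  out <- new_drying_series(rec, lpr0, drying_time)
  class(out) <- c("optimized_cycle", class(out))
  out
}
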