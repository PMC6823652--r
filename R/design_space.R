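#' Generate the primary-drying design space
#'
#' Evaluates the quasi-steady sublimation flux and vial-bottom temperature
#' over a grid of chamber pressures and shelf temperatures at a chosen stage
#' of drying, together with the critical product-temperature limit curve
#' (the shelf temperature and flux that pin the vial bottom at `t_pr_max`
#' for each pressure) and the equipment-capability flux. The conservative,
#' conventional choice is `stage = "end"`, where the cake resistance is at
#' its end-of-drying maximum.
#'
#' @param config A [drying_config()].
#' @param pch_grid Chamber pressures (Torr); default 25 log-spaced points in
#'   0.05--1 Torr.
#' @param tsh_grid Shelf temperatures (degC); default 17 points in -40--120.
#' @param stage Drying-stage fraction of the cake length in `[0, 1]`, or
#'   `"end"` (equivalent to 1).
#' @param t_pr_max Critical product temperature (degC); defaults to the
#'   formulation's.
#' @param cap An [equipment_capability()]; used to tabulate the capability
#'   flux per vial area.
#' @return An object of class `design_space`: list with `grid` (long data
#'   frame: pch, tsh, flux, t_bot), `limit` (per pch: tsh_limit, flux_limit),
#'   `capability` (per pch: flux), `stage`, `lck` and `lpr0`. Fluxes are in
#'   kg/(h m^2); cells without sublimation have zero flux.
#' @export
generate_design_space <- function(config,
                                  pch_grid = exp(seq(log(0.05), log(1),
                                                     length.out = 25)),
                                  tsh_grid = seq(-40, 120, length.out = 17),
                                  stage = "end",
                                  t_pr_max = config$form$t_pr_max,
                                  cap = equipment_capability(disabled = TRUE)) {
  stopifnot(inherits(config, "drying_config"))
  if (length(pch_grid) == 0 || length(tsh_grid) == 0)
    stop("grids must be nonempty")
  if (is.unsorted(pch_grid, strictly = TRUE) ||
      is.unsorted(tsh_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  frac <- if (identical(stage, "end")) 1 else stage
  if (!is.numeric(frac) || frac < 0 || frac > 1)
    stop("stage must be a fraction in [0, 1] or \"end\"")
  lpr0 <- initial_frozen_length(config$vfill, config$form, config$vial$ap)
  lck <- frac * lpr0

  # g/(cm^2 h) -> kg/(h m^2): * 1e-3 kg/g * 1e4 cm^2/m^2
  to_kg_m2 <- 10
  cells <- expand.grid(pch = pch_grid, tsh = tsh_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(p, ts) {
    st <- quasi_steady_solve(lck, lpr0, ts, p, config)
    c(st$flux, st$t_bot)
  }, cells$pch, cells$tsh)
  cells$flux <- res[1, ] * to_kg_m2
  cells$t_bot <- res[2, ]

  limit <- do.call(rbind, lapply(pch_grid, function(p) {
    st <- qs_solve_pinned(t_pr_max, p, lck, lpr0, config$form,
                          config$constants)
    kv <- kv_of_pressure(config$htm, p)
    data.frame(pch = p,
               tsh_limit = tsh_required_for(st$flux, t_pr_max, kv,
                                            config$vial, config$constants),
               flux_limit = st$flux * to_kg_m2)
  }))
  # capability kg/h total -> per-area kg/(h m^2): /(n_vials * ap in m^2)
  capability <- data.frame(
    pch = pch_grid,
    flux = equipment_capability_rate(cap, pch_grid) /
      (config$n_vials * config$vial$ap * 1e-4))

  structure(list(grid = cells, limit = limit, capability = capability,
                 stage = frac, lck = lck, lpr0 = lpr0,
                 t_pr_max = t_pr_max, config = config, cap = cap),
            class = "design_space")
}

#' Critical product-temperature limit trajectory
#'
#' Follows primary drying at a fixed chamber pressure with the vial-bottom
#' temperature pinned at the critical value: at each step the frozen-layer
#' conduction and cake vapor-transport legs determine the front temperature
#' and flux, the shelf temperature required to supply that heat is backed
#' out of the vial heat-transfer leg, and the front advances.
#'
#' @param config A [drying_config()]; its shelf schedule is ignored.
#' @param t_pr_max Pinned vial-bottom temperature (degC).
#' @param pch Fixed chamber pressure (Torr).
#' @return Data frame (t, lck, t_sub, flux, tsh_required); flux in
#'   g/(cm^2 h).
#' @export
product_limit_trajectory <- function(config, t_pr_max, pch) {
  stopifnot(inherits(config, "drying_config"))
  lpr0 <- initial_frozen_length(config$vfill, config$form, config$vial$ap)
  kv <- kv_of_pressure(config$htm, pch)
  dt <- config$dt
  t <- 0; lck <- 0
  rows <- list(); i <- 0L
  repeat {
    st <- qs_solve_pinned(t_pr_max, pch, lck, lpr0, config$form,
                          config$constants)
    if (st$flux <= 0)
      stop("no sublimation with the bottom pinned at ", t_pr_max,
           " degC: chamber pressure too high for this limit")
    i <- i + 1L
    rows[[i]] <- c(t = t, lck = lck, t_sub = st$t_sub, flux = st$flux,
                   tsh_required = tsh_required_for(st$flux, t_pr_max, kv,
                                                   config$vial,
                                                   config$constants))
    dlck <- st$flux * dt / config$form$rho_ice
    if (lck + dlck >= lpr0) break
    lck <- lck + dlck
    t <- t + dt
  }
  as.data.frame(do.call(rbind, rows))
}

#' Optimal constant setpoint from a design space
#'
#' The classical single-setpoint optimum: with an equipment capability line,
#' the chamber pressure where the product-temperature-limit flux equals the
#' capability flux (the intersection on the design-space chart); without
#' one, the pressure maximizing the product-limit flux subject to the shelf
#' temperature staying within `tsh_max`. Ties resolve to the lower pressure.
#'
#' @param ds A `design_space` from [generate_design_space()].
#' @param tsh_max Shelf-temperature ceiling (degC).
#' @return List `(pch, tsh, flux)`; flux in kg/(h m^2).
#' @export
optimal_setpoint <- function(ds, tsh_max = 120) {
  stopifnot(inherits(ds, "design_space"))
  lim <- ds$limit
  feasible <- lim$tsh_limit <= tsh_max
  cap_flux <- ds$capability$flux
  if (all(!feasible))
    stop("no feasible setpoint: shelf-temperature ceiling ", tsh_max,
         " degC binds at every grid pressure")
  if (any(is.finite(cap_flux)) && any(lim$flux_limit > cap_flux)) {
    # capability binds somewhere: intersection of limit curve and cap line
    diff_flux <- lim$flux_limit - cap_flux
    idx <- which(diff(sign(diff_flux)) != 0)
    if (length(idx) == 0)
      stop("capability line does not intersect the product-limit curve ",
           "on the pressure grid")
    i <- idx[1]
    # linear interpolation of the crossing
    w <- diff_flux[i] / (diff_flux[i] - diff_flux[i + 1])
    pch <- lim$pch[i] + w * (lim$pch[i + 1] - lim$pch[i])
    flux <- stats::approx(lim$pch, cap_flux, xout = pch)$y
    tsh <- stats::approx(lim$pch, pmin(lim$tsh_limit, tsh_max), xout = pch)$y
    return(list(pch = pch, tsh = tsh, flux = flux))
  }
  # capability non-binding: maximize the capped limit flux over pressure
  eff_flux <- ifelse(feasible, lim$flux_limit, NA)
  # where the ceiling binds, flux is what tsh_max can drive (free solve)
  for (j in which(!feasible)) {
    st <- quasi_steady_solve(ds$lck, ds$lpr0, tsh_max, lim$pch[j], ds$config)
    eff_flux[j] <- st$flux * 10
  }
  i <- which.max(eff_flux)  # which.max takes the first (lowest-pch) maximum
  # golden-section refinement around the coarse maximum
  lo <- lim$pch[max(i - 1L, 1L)]
  hi <- lim$pch[min(i + 1L, nrow(lim))]
  f <- function(p) {
    st <- qs_solve_pinned(ds$t_pr_max, p, ds$lck, ds$lpr0, ds$config$form,
                          ds$config$constants)
    kv <- kv_of_pressure(ds$config$htm, p)
    tsh <- tsh_required_for(st$flux, ds$t_pr_max, kv, ds$config$vial,
                            ds$config$constants)
    if (tsh > tsh_max) {
      st2 <- quasi_steady_solve(ds$lck, ds$lpr0, tsh_max, p, ds$config)
      return(st2$flux)
    }
    st$flux
  }
  opt <- stats::optimize(function(p) -f(p), c(lo, hi), tol = 1e-6)
  pch <- opt$minimum
  st <- qs_solve_pinned(ds$t_pr_max, pch, ds$lck, ds$lpr0, ds$config$form,
                        ds$config$constants)
  kv <- kv_of_pressure(ds$config$htm, pch)
  tsh <- min(tsh_required_for(st$flux, ds$t_pr_max, kv, ds$config$vial,
                              ds$config$constants), tsh_max)
  list(pch = pch, tsh = tsh, flux = -opt$objective * 10)
}
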