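#' Inputs for the 0D freezing calculator
#'
#' The freezing model treats the product as a single lumped thermal mass
#' exchanging heat with the shelf only: cooling of the liquid, a temperature
#' jump from the nucleation temperature to the equilibrium freezing
#' temperature, an isothermal crystallization hold while the latent-heat
#' budget is removed, and solid (ice) cooling.
#'
#' @param v Fill volume (cm^3).
#' @param av Vial heat-transfer area (cm^2).
#' @param h Shelf-to-product film heat-transfer coefficient
#'   (cal/(s K cm^2)).
#' @param t_n Nucleation temperature (degC); must satisfy `t_n <= t_f`.
#' @param t_f Equilibrium freezing temperature (degC).
#' @param t0 Initial product temperature (degC); defaults to the first shelf
#'   setpoint when `NULL`.
#' @param rho Liquid product density (g/cm^3).
#' @param cp_liquid,cp_ice Specific heats of liquid and ice (cal/(g K)).
#' @param hf Latent heat of fusion (cal/g).
#' @return An object of class `freezing_inputs`.
#' @export
freezing_inputs <- function(v, av, h, t_n, t_f = 0, t0 = NULL, rho = 1.0,
                            cp_liquid = 1.0, cp_ice = 0.503, hf = 79.7) {
  if (v <= 0) stop("fill volume must be > 0")
  if (h <= 0) stop("heat-transfer coefficient must be > 0")
  if (t_n > t_f) stop("nucleation temperature must not exceed t_f")
  if (hf <= cp_liquid * (t_f - t_n))
    stop("latent-heat budget nonpositive: hf <= cp_liquid*(t_f - t_n)")
  structure(list(v = v, av = av, h = h, t_n = t_n, t_f = t_f, t0 = t0,
                 rho = rho, cp_liquid = cp_liquid, cp_ice = cp_ice, hf = hf),
            class = "freezing_inputs")
}

#' Simulate the freezing stage
#'
#' Integrates the lumped-capacitance energy balance
#' \eqn{\rho C_p V \, dT_{pr}/dt = -h A_v (T_{pr} - T_{sh}(t))}
#' through three stages: liquid cooling until the nucleation temperature is
#' reached, an isothermal crystallization hold at `t_f` until the removed
#' heat equals the latent budget \eqn{\rho V (H_f - C_p (T_f - T_n))}, and
#' solid cooling with ice properties until the end of the shelf schedule.
#'
#' @param inp A [freezing_inputs()] object.
#' @param shelf Shelf-temperature schedule ([lyo_schedule()] or a constant,
#'   degC).
#' @param dt Time step (h); the explicit update is first-order and converges
#'   well below 0.5% change in stage durations at the default.
#' @param t_end End of simulation (h); defaults to the end of the schedule
#'   plus 2 h.
#' @return An object of class `freezing_result`: a list with the trajectory
#'   data frame `profile` (t, t_pr, stage), `t_nucleation_onset`,
#'   `crystallization_duration` and `t_end` (hours).
#' @export
#' @examples
#' inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -8, t0 = 20)
#' res <- simulate_freezing(inp, lyo_schedule(20, -20, rates = 1, holds = 3))
#' res$crystallization_duration
simulate_freezing <- function(inp, shelf, dt = 1e-3, t_end = NULL) {
  stopifnot(inherits(inp, "freezing_inputs"))
  if (dt <= 0) stop("dt must be > 0")
  shelf <- as_schedule(shelf)
  if (is.null(t_end)) t_end <- max(shelf$times) + 2
  t0 <- if (is.null(inp$t0)) shelf$values[1] else inp$t0

  n_max <- ceiling(t_end / dt) + 1L
  t_grid <- seq(0, by = dt, length.out = n_max)
  tsh <- schedule_value(shelf, t_grid)

  # per-hour cooling rate coefficients for liquid and solid stages
  kl <- inp$h * inp$av * .S_PER_H / (inp$rho * inp$cp_liquid * inp$v)
  ks <- inp$h * inp$av * .S_PER_H / (inp$rho * inp$cp_ice * inp$v)
  latent_budget <- inp$rho * inp$v * (inp$hf - inp$cp_liquid * (inp$t_f - inp$t_n))

  t_pr <- numeric(n_max)
  stage <- integer(n_max)
  t_pr[1] <- t0
  i <- 1L

  # stage 1: liquid cooling until nucleation
  t_nuc <- NA_real_
  while (i < n_max && t_pr[i] > inp$t_n) {
    t_pr[i + 1L] <- t_pr[i] - kl * (t_pr[i] - tsh[i]) * dt
    stage[i + 1L] <- 1L
    i <- i + 1L
  }
  stage[1] <- 1L
  if (t_pr[i] > inp$t_n) {
    warning("nucleation temperature not reached within the schedule; ",
            "returning truncated cooling-only result")
    prof <- data.frame(t = t_grid[1:i], t_pr = t_pr[1:i],
                       stage = "cooling")
    return(structure(list(profile = prof, t_nucleation_onset = NA_real_,
                          crystallization_duration = NA_real_,
                          t_end = t_grid[i]), class = "freezing_result"))
  }
  t_nuc <- t_grid[i]
  # temperature jumps to the equilibrium freezing point on nucleation; the
  # jump row opens the crystallization hold
  t_pr[i] <- inp$t_f
  stage[i] <- 2L

  # stage 2: isothermal crystallization until the latent budget is removed
  removed <- 0
  i_cryst0 <- i
  while (i < n_max && removed < latent_budget) {
    removed <- removed + inp$h * inp$av * .S_PER_H * (inp$t_f - tsh[i]) * dt
    t_pr[i + 1L] <- inp$t_f
    stage[i + 1L] <- 2L
    i <- i + 1L
  }
  cryst_dur <- t_grid[i] - t_grid[i_cryst0]

  # stage 3: solid cooling with ice properties
  while (i < n_max) {
    t_pr[i + 1L] <- t_pr[i] - ks * (t_pr[i] - tsh[i]) * dt
    stage[i + 1L] <- 3L
    i <- i + 1L
  }

  prof <- data.frame(t = t_grid[1:i], t_pr = t_pr[1:i],
                     stage = c("cooling", "crystallization",
                               "solid-cooling")[pmax(stage[1:i], 1L)])
  structure(list(profile = prof, t_nucleation_onset = t_nuc,
                 crystallization_duration = cryst_dur, t_end = t_grid[i]),
            class = "freezing_result")
}

#' Closed-form crystallization time at constant shelf temperature
#'
#' Solves the latent-heat balance
#' \eqn{\rho V (H_f - C_p (T_f - T_n)) = h A_v (T_f - T_{sh}) \Delta t}
#' for the crystallization duration.
#'
#' @param inp A [freezing_inputs()] object.
#' @param tsh Constant shelf temperature (degC); must be below `t_f`.
#' @return Crystallization duration (h).
#' @export
crystallization_time <- function(inp, tsh) {
  stopifnot(inherits(inp, "freezing_inputs"))
  if (tsh >= inp$t_f)
    stop("no driving force: shelf temperature must be below t_f")
  num <- inp$rho * inp$v * (inp$hf - inp$cp_liquid * (inp$t_f - inp$t_n))
  num / (inp$h * inp$av * (inp$t_f - tsh)) / .S_PER_H
}

#' Fit the shelf-to-product film coefficient from measured cooling data
#'
#' Estimates `h` by nonlinear least squares between the measured
#' pre-nucleation product temperatures and the stage-1 cooling prediction of
#' [simulate_freezing()] under the given shelf schedule.
#'
#' @param measured Data frame with columns `t` (h) and `t_pr` (degC),
#'   covering the cooling segment only (all `t_pr` above `t_n`).
#' @param shelf Shelf schedule.
#' @param inp A [freezing_inputs()] object; its `h` is ignored.
#' @param interval Search interval for `h` (cal/(s K cm^2)).
#' @return Fitted `h` (cal/(s K cm^2)) with attribute `"rss"`.
#' @export
fit_film_coefficient <- function(measured, shelf, inp,
                                 interval = c(1e-6, 1e-1)) {
  stopifnot(inherits(inp, "freezing_inputs"))
  if (!all(c("t", "t_pr") %in% names(measured)))
    stop("measured must have columns t and t_pr")
  if (nrow(measured) < 3) stop("need at least 3 measured points")
  if (stats::sd(measured$t_pr) == 0)
    stop("measured series is constant: no cooling signal to fit h")
  shelf <- as_schedule(shelf)
  t0 <- measured$t_pr[which.min(measured$t)]

  predict_cooling <- function(h) {
    # stage-1 trajectory on a fine grid, interpolated at measurement times
    dt <- min(1e-3, diff(range(measured$t)) / 200)
    tg <- seq(0, max(measured$t) + dt, by = dt)
    tsh <- schedule_value(shelf, tg)
    kl <- h * inp$av * .S_PER_H / (inp$rho * inp$cp_liquid * inp$v)
    tp <- numeric(length(tg))
    tp[1] <- t0
    for (i in seq_len(length(tg) - 1L))
      tp[i + 1L] <- tp[i] - kl * (tp[i] - tsh[i]) * dt
    stats::approx(tg, tp, xout = measured$t, rule = 2)$y
  }
  obj <- function(log_h) sum((predict_cooling(exp(log_h)) - measured$t_pr)^2)
  opt <- stats::optimize(obj, interval = log(interval), tol = 1e-10)
  h_fit <- exp(opt$minimum)
  if (h_fit <= interval[1] * 1.01 || h_fit >= interval[2] * 0.99)
    warning("fitted h lies at the edge of the search interval")
  structure(h_fit, rss = opt$objective)
}

#' Biot number diagnostic for the lumped-capacitance assumption
#'
#' @param h Heat-transfer coefficient (cal/(s K cm^2)).
#' @param lc Characteristic length (cm), the larger of fill height and vial
#'   diameter.
#' @param k Product thermal conductivity (cal/(s cm K)).
#' @return Bi = h lc / k. A warning is emitted when Bi > 0.1, the usual
#'   validity cut-off of the lumped-capacitance method.
#' @export
biot_number <- function(h, lc, k) {
  if (any(c(h, lc, k) <= 0)) stop("h, lc and k must all be > 0")
  bi <- h * lc / k
  if (bi > 0.1)
    warning(sprintf(
      "Bi = %.3g > 0.1: lumped-capacitance error may be significant", bi))
  bi
}
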