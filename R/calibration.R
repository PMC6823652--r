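#' Fit the vial heat-transfer coefficient to an experimental drying time
#'
#' Primary-drying simulation runs are monotone in Kv: more heat dries the
#' product faster. The fitted Kv is the fixed value whose simulated drying
#' time matches the experimental one (typically determined from Pirani /
#' capacitance-manometer convergence), found by bracketed root search.
#'
#' @param config A [drying_config()]; its heat-transfer model is replaced by
#'   the candidate fixed Kv during the search.
#' @param t_exp Experimental drying time (h).
#' @param interval Search bracket for Kv (cal/(s K cm^2)).
#' @param tol Match tolerance on drying time (h).
#' @return Fitted Kv (cal/(s K cm^2)) with attribute `"drying_time"`.
#' @export
fit_kv_to_drying_time <- function(config, t_exp, interval = c(1e-5, 1e-2),
                                  tol = 1e-3) {
  stopifnot(inherits(config, "drying_config"))
  if (t_exp <= 0) stop("experimental drying time must be > 0 h")
  sim_time <- function(kv) {
    cfg <- config
    cfg$htm <- heat_transfer_model(fixed_kv = kv)
    simulate_primary_drying(cfg)$drying_time
  }
  t_hi <- sim_time(interval[1])  # low Kv -> slow drying
  t_lo <- sim_time(interval[2])
  if (t_exp > t_hi || t_exp < t_lo)
    stop(sprintf(
      "t_exp = %.3f h outside achievable range [%.3f, %.3f] h on the Kv bracket",
      t_exp, t_lo, t_hi))
  f <- function(kv) sim_time(kv) - t_exp
  # bisection on the monotone map Kv -> drying time
  lo <- interval[1]; hi <- interval[2]
  flo <- t_hi - t_exp
  for (iter in 1:200) {
    mid <- sqrt(lo * hi)  # Kv spans decades: bisect in log space
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-12) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  structure(mid, drying_time = fm + t_exp)
}

#' Fit the (Kc, Kp, KD) pressure dependence of Kv
#'
#' Least-squares fit of \eqn{K_v = K_c + K_p P_{ch} / (1 + K_D P_{ch})} to
#' calibration points, e.g. Kv values fitted to drying times at several
#' chamber pressures. With exactly three distinct pressures the system is
#' exactly determined and the residual is ~0.
#'
#' @param pch Chamber pressures (Torr), at least 3 distinct values.
#' @param kv Corresponding Kv values (cal/(s K cm^2)).
#' @return Named vector `c(kc, kp, kd)` with attribute `"residual"` (RSS).
#'   A warning is raised if the fitted `kd` is negative (extrapolation
#'   outside the data is then unsafe).
#' @export
#' @examples
#' fit_kv_pressure_curve(c(0.1, 0.3, 1.5), c(3.6e-4, 5.1e-4, 10.67e-4))
fit_kv_pressure_curve <- function(pch, kv) {
  if (length(pch) != length(kv)) stop("pch and kv lengths differ")
  if (length(unique(pch)) < 3) stop("need >= 3 distinct pressures")
  # initial guess: kc near the low-pressure limit, kp from the secant
  # through the extreme points, kd order 1
  o <- order(pch)
  p1 <- pch[o][1]; p2 <- pch[o][length(pch)]
  k1 <- kv[o][1]; k2 <- kv[o][length(kv)]
  start <- c(kc = max(min(kv) * 0.9, 1e-8),
             kp = max((k2 - k1) / (p2 - p1), 1e-8), kd = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) par[1] + par[2] * pch / (1 + par[3] * pch) - kv,
    lower = c(0, 0, -1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info < 1 || fit$info > 4)
    stop("Kv pressure-curve fit did not converge: ", fit$message)
  co <- fit$par
  if (co[["kd"]] < 0)
    warning("fitted kd < 0: extrapolation beyond the data is unsafe")
  structure(c(kc = co[["kc"]], kp = co[["kp"]], kd = co[["kd"]]),
            residual = fit$deviance)
}

#' Extract the product-resistance profile from a measured temperature trace
#'
#' Inverts the quasi-steady balance sample by sample: with Kv known, the
#' instantaneous heat flow follows from the shelf-to-bottom temperature
#' difference, the sublimation flux from the heat of sublimation, the front
#' temperature from conduction through the remaining frozen layer, and the
#' resistance from the vapor-pressure driving force. The cake length is
#' advanced by the running flux integral, keeping the extraction
#' self-consistent.
#'
#' @param measured Data frame with columns `t` (h) and `t_bot` (degC)
#'   covering primary drying.
#' @param config A [drying_config()] with a known heat-transfer model.
#' @return Data frame of class `rp_profile` with columns `t`, `lck` (cm) and
#'   `rp` (cm^2 h Torr/g). Samples with nonpositive flux or front pressure
#'   not exceeding chamber pressure are dropped with a warning.
#' @export
rp_profile_from_temperature <- function(measured, config) {
  stopifnot(inherits(config, "drying_config"))
  if (!all(c("t", "t_bot") %in% names(measured)))
    stop("measured must have columns t and t_bot")
  geom <- config$vial
  const <- config$constants
  lpr0 <- initial_frozen_length(config$vfill, config$form, geom$ap)
  kice_h <- const$k_ice * .S_PER_H

  n <- nrow(measured)
  lck <- 0
  out <- vector("list", n)
  dropped <- 0L
  t_prev <- measured$t[1]
  for (i in seq_len(n)) {
    ti <- measured$t[i]
    tbot <- measured$t_bot[i]
    tsh <- schedule_value(config$shelf, ti)
    pch <- schedule_value(config$pressure, ti)
    kv <- kv_of_pressure(config$htm, pch)
    q <- kv * .S_PER_H * geom$av * (tsh - tbot)     # cal/h
    flux <- q / (const$dhs * geom$ap)               # g/(cm^2 h)
    lpr <- max(lpr0 - lck, 0)
    t_sub <- tbot - q * lpr / (kice_h * geom$ap)
    p_sub <- const$vp_a * exp(-const$vp_b / (t_sub + 273.15))
    if (flux > 0 && p_sub > pch) {
      out[[i]] <- c(t = ti, lck = lck, rp = (p_sub - pch) / flux)
    } else {
      dropped <- dropped + 1L
    }
    if (i < n) {
      dt_i <- measured$t[i + 1L] - ti
      lck <- min(lck + max(flux, 0) * dt_i / config$form$rho_ice, lpr0)
    }
  }
  if (dropped > 0L)
    warning(dropped, " sample(s) dropped (no sublimation driving force)")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    stop("all samples dropped: trace shows no sublimation")
  structure(as.data.frame(do.call(rbind, out)),
            class = c("rp_profile", "data.frame"))
}

#' Fit the cake-resistance curve to an Rp profile
#'
#' Nonnegative-constrained least squares of
#' \eqn{R_p = R_0 + A_1 L_{ck} / (1 + A_2 L_{ck})}.
#'
#' @param profile Data frame with columns `lck` (cm) and `rp`
#'   (cm^2 h Torr/g), e.g. from [rp_profile_from_temperature()].
#' @return Named vector `c(r0, a1, a2)` with attribute `"residual"` (RSS).
#' @export
fit_rp_curve <- function(profile) {
  if (!all(c("lck", "rp") %in% names(profile)))
    stop("profile must have columns lck and rp")
  if (nrow(profile) < 3) stop("need >= 3 points to fit (r0, a1, a2)")
  l <- profile$lck
  r <- profile$rp
  lspan <- diff(range(l))
  slope <- if (lspan > 0) max((max(r) - min(r)) / lspan, 1e-8) else 1e-8
  fit <- minpack.lm::nls.lm(
    par = c(r0 = max(min(r), 1e-6), a1 = slope, a2 = 0.5),
    fn = function(par) par[1] + par[2] * l / (1 + par[3] * l) - r,
    lower = c(1e-12, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  if (fit$info < 1 || fit$info > 4)
    stop("cake-resistance curve fit did not converge: ", fit$message)
  co <- fit$par
  structure(c(r0 = co[["r0"]], a1 = co[["a1"]], a2 = co[["a2"]]),
            residual = fit$deviance)
}
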