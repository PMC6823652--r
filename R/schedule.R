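#' Setpoint schedules for shelf temperature and chamber pressure
#'
#' A schedule is a piecewise-linear setpoint trajectory built from ordered
#' segments of (target, ramp rate, hold). Starting from `initial`, each
#' segment ramps linearly to its target at `rate` (units per minute) and then
#' holds for `hold_h` hours. Beyond the last segment the final value is held
#' indefinitely, so a schedule is defined for all t >= 0.
#'
#' @param initial Value at t = 0 (degC for shelf, Torr for pressure).
#' @param targets Numeric vector of segment targets.
#' @param rates Ramp rates (units/min), recycled; use `Inf` for step changes.
#' @param holds Hold durations after each ramp (h), recycled.
#' @return An object of class `lyo_schedule`.
#' @export
#' @examples
#' # shelf held at -5 degC, then ramped at 1 degC/min to 30 degC and held
#' sh <- lyo_schedule(-5, targets = 30, rates = 1, holds = 24)
#' schedule_value(sh, c(0, 0.25, 1))
lyo_schedule <- function(initial, targets = numeric(), rates = 1,
                         holds = 0) {
  n <- length(targets)
  rates <- rep_len(rates, max(n, 1))
  holds <- rep_len(holds, max(n, 1))
  t <- 0
  val <- initial
  times <- 0
  values <- initial
  if (n > 0) {
    for (i in seq_len(n)) {
      if (rates[i] <= 0) stop("ramp rates must be > 0 (use Inf for steps)")
      ramp_h <- abs(targets[i] - val) / rates[i] / 60
      if (ramp_h > 0) {
        t <- t + ramp_h
        times <- c(times, t)
        values <- c(values, targets[i])
      } else if (targets[i] != val) { # instantaneous step
        times <- c(times, t + 1e-12)
        values <- c(values, targets[i])
        t <- t + 1e-12
      }
      val <- targets[i]
      if (holds[i] > 0) {
        t <- t + holds[i]
        times <- c(times, t)
        values <- c(values, val)
      }
    }
  }
  structure(list(times = times, values = values), class = "lyo_schedule")
}

#' Constant schedule
#' @param value The constant setpoint.
#' @return A `lyo_schedule` holding `value` for all time.
#' @export
schedule_constant <- function(value) lyo_schedule(value)

#' Tabulated schedule
#'
#' Build a schedule directly from (time, value) breakpoints with linear
#' interpolation between them and constant extrapolation outside.
#'
#' @param times Breakpoint times (h), strictly increasing, starting at 0.
#' @param values Setpoint values at the breakpoints.
#' @return A `lyo_schedule`.
#' @export
schedule_table <- function(times, values) {
  if (length(times) != length(values) || length(times) < 1)
    stop("times and values must have equal positive length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  structure(list(times = times, values = values), class = "lyo_schedule")
}

#' Evaluate a schedule
#' @param sched A `lyo_schedule` (a bare number is treated as constant).
#' @param t Time(s) in hours.
#' @return Setpoint value(s) at `t`.
#' @export
schedule_value <- function(sched, t) {
  sched <- as_schedule(sched)
  if (length(sched$times) == 1) return(rep(sched$values, length(t)))
  stats::approx(sched$times, sched$values, xout = t, rule = 2)$y
}

# coerce numbers to constant schedules so config fields accept either
as_schedule <- function(x) {
  if (inherits(x, "lyo_schedule")) return(x)
  if (is.numeric(x) && length(x) == 1) return(schedule_constant(x))
  stop("expected a lyo_schedule or a single number")
}

#' @export
print.lyo_schedule <- function(x, ...) {
  cat("Setpoint schedule:\n")
  print(data.frame(t_h = x$times, value = x$values), row.names = FALSE)
  invisible(x)
}
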