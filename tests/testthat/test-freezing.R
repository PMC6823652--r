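test_that("pre-nucleation cooling matches the exponential closed form", {
  inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -8, t_f = 0,
                         t0 = 20)
  tsh <- -20
  res <- simulate_freezing(inp, schedule_constant(tsh), dt = 1e-4,
                           t_end = 3)
  cool <- res$profile[res$profile$stage == "cooling", ]
  tau <- inp$h * inp$av * 3600 / (inp$rho * inp$cp_liquid * inp$v)
  exact <- tsh + (20 - tsh) * exp(-tau * cool$t)
  # error scaled by the driving temperature span
  expect_lt(max(abs(cool$t_pr - exact)) / (20 - tsh), 1e-4)
  # monotone decay toward the shelf temperature
  expect_true(all(diff(cool$t_pr) < 0))
})

test_that("crystallization hold matches the latent-budget closed form", {
  inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -8, t_f = 0,
                         t0 = 20)
  dt <- 1e-3
  res <- simulate_freezing(inp, schedule_constant(-20), dt = dt, t_end = 8)
  dt_closed <- crystallization_time(inp, -20)
  # direct evaluation of the energy balance as an independent check
  hand <- inp$rho * inp$v * (inp$hf - inp$cp_liquid * (0 - (-8))) /
    (inp$h * inp$av * (0 - (-20))) / 3600
  expect_equal(dt_closed, hand, tolerance = 1e-12)
  expect_lt(abs(res$crystallization_duration - dt_closed), 2 * dt)
  # inverse proportionality in h*Av
  inp2 <- freezing_inputs(v = 2, av = 3.8, h = 8e-4, t_n = -8, t_f = 0)
  expect_equal(crystallization_time(inp2, -20), dt_closed / 2)
  # zero latent budget edge: hf exactly consumed by supercooling rejected
  expect_error(freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -80,
                               t_f = 0, hf = 79.7), "budget")
  expect_error(crystallization_time(inp, 5), "driving force")
})

test_that("stage sequence and energy audit hold under a ramped shelf", {
  inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -8, t_f = 0,
                         t0 = 20)
  shelf <- lyo_schedule(20, targets = -20, rates = 1, holds = 4)
  dt <- 1e-3
  res <- simulate_freezing(inp, shelf, dt = dt)
  stages <- rle(res$profile$stage)$values
  expect_identical(stages, c("cooling", "crystallization", "solid-cooling"))
  # product temperature is pinned at t_f during the hold
  expect_true(all(res$profile$t_pr[res$profile$stage == "crystallization"]
                  == inp$t_f))
  # final product temperature converges to the shelf temperature
  expect_lt(abs(utils::tail(res$profile$t_pr, 1) - (-20)), 0.5)
  # energy audit: heat removed during the hold equals the latent budget
  cry <- res$profile[res$profile$stage == "crystallization", ]
  removed <- sum(inp$h * inp$av * 3600 *
                   (inp$t_f - schedule_value(shelf, cry$t)) * dt)
  budget <- inp$rho * inp$v * (inp$hf - inp$cp_liquid * (inp$t_f - inp$t_n))
  step_heat <- inp$h * inp$av * 3600 * (inp$t_f - (-20)) * dt
  expect_lt(abs(removed - budget), 2 * step_heat)
})

test_that("halving dt changes stage durations by less than 0.5%", {
  inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -8, t_f = 0,
                         t0 = 20)
  shelf <- lyo_schedule(20, targets = -20, rates = 1, holds = 4)
  a <- simulate_freezing(inp, shelf, dt = 1e-3)
  b <- simulate_freezing(inp, shelf, dt = 5e-4)
  expect_lt(rel_dev(a$t_nucleation_onset, b$t_nucleation_onset), 5e-3)
  expect_lt(rel_dev(a$crystallization_duration, b$crystallization_duration),
            5e-3)
})

test_that("film-coefficient fit recovers truth, noiselessly and with noise", {
  h_true <- 4e-4
  inp <- freezing_inputs(v = 2, av = 3.8, h = h_true, t_n = -8, t_f = 0,
                         t0 = 20)
  shelf <- lyo_schedule(20, targets = -20, rates = 1, holds = 4)
  t_nuc <- simulate_freezing(inp, shelf)$t_nucleation_onset
  prof <- generate_synthetic_profile(list(inputs = inp, shelf = shelf),
                                     noise_sd = 0, every = 25)
  cooling <- prof[prof$t < 0.95 * t_nuc, ]
  fit <- fit_film_coefficient(cooling, shelf, inp)
  expect_lt(rel_dev(as.numeric(fit), h_true), 1e-3)

  noisy <- generate_synthetic_profile(list(inputs = inp, shelf = shelf),
                                      noise_sd = 0.3, seed = 7, every = 25)
  noisy <- noisy[noisy$t < 0.95 * t_nuc, ]
  fit_n <- fit_film_coefficient(noisy, shelf, inp)
  expect_lt(rel_dev(as.numeric(fit_n), h_true), 0.05)

  flat <- data.frame(t = 1:5, t_pr = rep(5, 5))
  expect_error(fit_film_coefficient(flat, shelf, inp), "constant")
  expect_error(fit_film_coefficient(cooling[1:2, ], shelf, inp), "3")
})

test_that("Biot number diagnoses the lumped-capacitance regime", {
  expect_equal(suppressWarnings(biot_number(1, 1, 1)), 1)
  expect_equal(suppressWarnings(biot_number(0.01, 4, 1)),
               2 * suppressWarnings(biot_number(0.01, 2, 1)))
  # water-filled vial during cooling: Bi well above the 0.1 cut-off
  expect_warning(bi <- biot_number(4e-4, 2.0, 0.00143), "lumped")
  expect_gt(bi, 0.3)
  expect_error(biot_number(-1, 1, 1), "must all be")
})

test_that("unreached nucleation yields a truncated cooling-only result", {
  inp <- freezing_inputs(v = 2, av = 3.8, h = 4e-4, t_n = -30, t_f = 0,
                         t0 = 20)
  expect_warning(
    res <- simulate_freezing(inp, schedule_constant(-20), t_end = 2),
    "not reached")
  expect_true(all(res$profile$stage == "cooling"))
  expect_true(is.na(res$crystallization_duration))
})
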