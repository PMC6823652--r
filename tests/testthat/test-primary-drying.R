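test_that("quasi-steady solver agrees with the brute-force oracle", {
  cfg <- mannitol_6r_config(shelf = -5, pressure = 0.3,
                            htm = heat_transfer_model(fixed_kv = 5.1e-4))
  lpr0 <- initial_frozen_length(2, cfg$form, cfg$vial$ap)
  for (lck in c(0, 0.2, 0.5) * lpr0) {
    st <- quasi_steady_solve(lck, lpr0, -5, 0.3, cfg)
    or <- oracle_quasi_steady(-5, 0.3, lck, lpr0, 5.1e-4,
                              cfg$vial$av, cfg$vial$ap)
    expect_equal(st$t_sub, or$t_sub, tolerance = 1e-6)
    expect_equal(st$t_bot, or$t_bot, tolerance = 1e-6)
    expect_equal(st$flux, or$flux, tolerance = 1e-6)
  }
})

test_that("three heat-flow expressions agree to 1e-9 at solved states", {
  cfg <- mannitol_6r_config(shelf = -5, pressure = 0.3)
  lpr0 <- initial_frozen_length(2, cfg$form, cfg$vial$ap)
  const <- cfg$constants
  for (case in list(c(-5, 0.3, 0), c(-5, 0.15, 0.3), c(20, 0.1, 0.5),
                    c(-20, 0.05, 0.1))) {
    tsh <- case[1]; pch <- case[2]; lck <- case[3] * lpr0
    st <- quasi_steady_solve(lck, lpr0, tsh, pch, cfg)
    kv <- kv_of_pressure(cfg$htm, pch)
    q1 <- (tsh - st$t_bot) * kv * 3600 * cfg$vial$av
    q2 <- (st$t_bot - st$t_sub) * cfg$vial$ap * const$k_ice * 3600 /
      (lpr0 - lck)
    q3 <- (st$p_sub - pch) * cfg$vial$ap * const$dhs /
      rp_of_cake_length(cfg$form, lck)
    expect_lt(abs(q1 - q3) / q3, 1e-9)
    expect_lt(abs(q2 - q3) / q3, 1e-9)
  }
})

test_that("insulated-front and vanishing-frozen-layer limits hold", {
  # enormous cake resistance: no flux, bottom equilibrates with shelf
  stiff <- formulation(0.05, r0 = 1e9, a1 = 0, a2 = 0, rho_solute = 1.52)
  cfg <- drying_config(vial_6r(), stiff, heat_transfer_model(fixed_kv = 5e-4),
                       2, -5, 0.3)
  lpr0 <- initial_frozen_length(2, stiff, cfg$vial$ap)
  st <- quasi_steady_solve(0, lpr0, -5, 0.3, cfg)
  expect_lt(st$flux, 1e-6)
  expect_lt(abs(st$t_bot - (-5)), 0.01)

  # frozen layer gone: bottom and front coincide
  cfg2 <- mannitol_6r_config()
  lpr0 <- initial_frozen_length(2, cfg2$form, cfg2$vial$ap)
  st2 <- quasi_steady_solve(lpr0, lpr0, -5, 0.3, cfg2)
  expect_lt(abs(st2$t_bot - st2$t_sub), 1e-6)

  # no sublimation fixed point: cold shelf, high chamber pressure
  st3 <- quasi_steady_solve(0, lpr0, -40, 0.5, cfg2)
  expect_identical(st3$flux, 0)
  expect_equal(st3$t_bot, -40)
  expect_error(quasi_steady_solve(lpr0 + 0.1, lpr0, -5, 0.3, cfg2), "lck")
})

test_that("drying run conserves mass and reports interpolated end time", {
  cfg <- mannitol_6r_config(htm = heat_transfer_model(fixed_kv = 5.1e-4))
  res <- simulate_primary_drying(cfg)
  # sublimed mass equals the initial ice inventory within one step's flux*dt
  sub_mass <- sum(res$profile$flux * cfg$vial$ap * cfg$dt)
  ice_mass <- cfg$form$rho_ice * cfg$vial$ap * res$lpr0
  expect_lt(abs(sub_mass - ice_mass),
            max(res$profile$flux) * cfg$vial$ap * cfg$dt)
  # lck nondecreasing from 0, flux nonincreasing under constant setpoints
  expect_true(all(diff(res$profile$lck) >= 0))
  expect_identical(res$profile$lck[1], 0)
  expect_true(all(diff(res$profile$flux) <= 1e-12))
  # small fill dries quickly
  cfg_small <- mannitol_6r_config(vfill = 0.05,
                                  htm = heat_transfer_model(fixed_kv = 5.1e-4))
  expect_lt(simulate_primary_drying(cfg_small)$drying_time,
            res$drying_time / 10)
  # impossible drying flagged at once
  expect_error(simulate_primary_drying(mannitol_6r_config(shelf = -40,
                                                          pressure = 1)),
               "no sublimation")
})

test_that("drying time is monotone in shelf temperature and Kv", {
  times_tsh <- vapply(c(-10, -5, 0, 10), function(ts)
    simulate_primary_drying(mannitol_6r_config(shelf = ts))$drying_time,
    numeric(1))
  expect_true(all(diff(times_tsh) < 0))
  times_kv <- vapply(c(3e-4, 5e-4, 8e-4), function(kv)
    simulate_primary_drying(
      mannitol_6r_config(htm = heat_transfer_model(fixed_kv = kv))
    )$drying_time, numeric(1))
  expect_true(all(diff(times_kv) < 0))
  # max product temperature nondecreasing in shelf temperature
  tb <- vapply(c(-10, -5, 0, 10), function(ts)
    simulate_primary_drying(mannitol_6r_config(shelf = ts))$max_t_bot,
    numeric(1))
  expect_true(all(diff(tb) > 0))
})

test_that("division stepping converges to the time-stepping limit", {
  cfg <- mannitol_6r_config(htm = heat_transfer_model(fixed_kv = 5.1e-4))
  t_ref <- simulate_primary_drying(cfg)$drying_time
  d1 <- simulate_primary_drying_by_divisions(cfg, 1)
  # single division is the rectangle rule at initial flux
  expect_equal(d1$drying_time,
               d1$lpr0 * cfg$form$rho_ice / d1$profile$flux[1])
  t_div <- vapply(c(10, 100, 1000), function(n)
    simulate_primary_drying_by_divisions(cfg, n)$drying_time, numeric(1))
  # coarse divisions underestimate; refinement increases toward the limit
  expect_true(all(diff(t_div) > 0))
  expect_lt(rel_dev(t_div[3], t_ref), 5e-3)
  expect_error(simulate_primary_drying_by_divisions(cfg, 0), "n_divisions")
})

test_that("shelf ramp is honored during drying", {
  sh <- lyo_schedule(-5, targets = 30, rates = 1, holds = 48)
  cfg <- mannitol_6r_config(shelf = sh, pressure = 0.15)
  res <- simulate_primary_drying(cfg)
  # shelf reaches 30 degC after 35 min of ramp
  expect_equal(schedule_value(sh, 35 / 60), 30)
  expect_lt(schedule_value(sh, 0.25), 30)
  # ramped start dries slower than an instant 30 degC shelf
  t_const <- simulate_primary_drying(
    mannitol_6r_config(shelf = 30, pressure = 0.15))$drying_time
  expect_gt(res$drying_time, t_const)
})
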