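test_that("Kv pressure curve evaluates, bounds and monotonicity hold", {
  htm <- htm_6r()
  expect_equal(kv_of_pressure(htm, 0.3), 5.10e-4, tolerance = 2e-3)
  # 5800 W vial coefficients at 100 mTorr
  htm58 <- heat_transfer_model(kc = 2.64e-4, kp = 33.2e-4, kd = 3.64)
  expect_equal(kv_of_pressure(htm58, 0.1), 5.07e-4, tolerance = 2e-3)
  # zero-pressure limit is the contact/radiation term
  expect_identical(kv_of_pressure(htm, 0), htm$kc)
  # fixed-Kv variant ignores pressure
  fx <- heat_transfer_model(fixed_kv = 5.1e-4)
  expect_equal(kv_of_pressure(fx, c(0, 0.5, 2)), rep(5.1e-4, 3))
  expect_error(kv_of_pressure(htm, -0.1), "pressure")

  # nondecreasing in pressure and bounded by kc + kp/kd on random draws
  set.seed(42)
  for (i in 1:20) {
    m <- heat_transfer_model(kc = runif(1, 1e-5, 1e-3),
                             kp = runif(1, 1e-5, 1e-2),
                             kd = runif(1, 0.1, 10))
    p <- sort(runif(50, 0, 5))
    kv <- kv_of_pressure(m, p)
    expect_true(all(diff(kv) >= -1e-15))
    expect_true(all(kv <= m$kc + m$kp / m$kd + 1e-15))
  }
})

test_that("cake resistance curve matches hand values and is concave", {
  mann <- mannitol_formulation()
  expect_identical(rp_of_cake_length(mann, 0), 1.4)
  expect_equal(rp_of_cake_length(mann, 0.35), 1.4 + 16 * 0.35)
  suc <- sucrose_formulation()
  expect_equal(rp_of_cake_length(suc, 0.5),
               0.208 + 15.29 * 0.5 / (1 + 1.6 * 0.5))
  expect_error(rp_of_cake_length(mann, -1), "cake length")

  # nondecreasing and concave on a grid for a2 >= 0
  l <- seq(0, 2, length.out = 200)
  for (a2 in c(0, 0.5, 3)) {
    f <- formulation(0.05, r0 = 0.5, a1 = 10, a2 = a2)
    r <- rp_of_cake_length(f, l)
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(diff(diff(r)) <= 1e-12))
  }
})

test_that("ice vapor pressure is near the triple point and increasing", {
  expect_equal(ice_vapor_pressure(273.15), 4.58, tolerance = 0.01)
  expect_lt(ice_vapor_pressure(250), ice_vapor_pressure(260))
  expect_lt(suppressWarnings(ice_vapor_pressure(160)), 1e-6)
  expect_error(ice_vapor_pressure(-5), "positive")
  expect_warning(ice_vapor_pressure(300), "150-280")
})

test_that("initial frozen length reproduces the closed form and is linear", {
  mann <- mannitol_formulation()
  ap <- pi # 20 mm inner diameter
  expect_equal(initial_frozen_length(2, mann, ap), 0.69162,
               tolerance = 1e-4)
  # hand-computed closed form to 1e-6 relative
  hand <- 2 / (ap * 0.918) * (1 - 0.05 * (1 - 0.918) / 1.52)
  expect_equal(initial_frozen_length(2, mann, ap), hand, tolerance = 1e-6)
  expect_equal(initial_frozen_length(4, mann, ap),
               2 * initial_frozen_length(2, mann, ap))
  # pure ice fill: lpr0 = vfill / ap
  ice <- suppressWarnings(
    formulation(0, r0 = 1, rho_solution = 0.918, rho_ice = 0.918))
  expect_equal(initial_frozen_length(3, ice, 2), 1.5)
  expect_error(initial_frozen_length(2, mann, 0), "area")
})

test_that("equipment capability line and disabled contract", {
  expect_equal(equipment_capability_rate(equipment_capability(0, 0), 0.7), 0)
  expect_equal(equipment_capability_rate(equipment_capability(0.1, 2), 0.15),
               0.4)
  expect_identical(
    equipment_capability_rate(equipment_capability(disabled = TRUE), 0.1),
    Inf)
  expect_error(
    equipment_capability_rate(equipment_capability(a = -1, b = 0.1), 0.5),
    "negative")
})

test_that("geometry areas follow the outer/inner diameter convention", {
  v <- vial_6r()
  expect_equal(v$av, pi * 1.1^2)
  expect_equal(v$ap, pi * 1.0^2)
  expect_gte(v$av, v$ap)
  expect_error(vial_geometry(20, 22), "inner_diameter")
})

test_that("unit conversions reproduce dual-unit table pairs and round-trip", {
  expect_equal(convert_units(2.75e-4, "cal/s/K/cm2", "W/m2/K"), 11.51,
               tolerance = 5e-3)
  expect_equal(convert_units(0.46, "1/Torr", "1/Pa"), 3.45e-3,
               tolerance = 5e-3)
  expect_equal(convert_units(8.93e-4, "cal/s/K/cm2/Torr", "W/m2/K/Pa"), 0.28,
               tolerance = 5e-3)
  expect_equal(convert_units(300, "mTorr", "Torr"), 0.3)
  expect_equal(convert_units(0, "degC", "K"), 273.15)
  expect_equal(convert_units(2.5, "kg/h", "g/h"), 2500)
  # round trips to 1e-12 relative over all supported pairs
  pairs <- list(c("Torr", "mTorr"), c("Torr", "Pa"), c("1/Torr", "1/Pa"),
                c("cal/s/K/cm2", "W/m2/K"),
                c("cal/s/K/cm2/Torr", "W/m2/K/Pa"), c("degC", "K"),
                c("kg/h", "g/h"))
  for (p in pairs) {
    x <- 3.7
    expect_equal(convert_units(convert_units(x, p[1], p[2]), p[2], p[1]), x,
                 tolerance = 1e-12)
  }
  expect_error(convert_units(1, "Torr", "K"), "dimensions")
  expect_error(convert_units(1, "psi", "Torr"), "supported")
})
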