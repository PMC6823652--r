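# lyodry

Simulation and optimization of pharmaceutical freeze-drying (lyophilization)
cycles, for process engineers and formulation scientists who need to design,
transfer or shorten primary drying without weeks of trial runs.

## What it computes

Primary drying — sublimation of ice from the frozen product under vacuum —
is governed by a quasi-steady balance between three transport legs that must
carry the same heat flow:

    Q̇ = (Tsh − Tbot) · Kv · Av
       = (Tbot − Tsub) · Ap · k_ice / Lpr
       = (Psub − Pch) · Ap · ΔHs / Rp

with the pressure-dependent vial heat-transfer coefficient
`Kv = Kc + Kp·Pch / (1 + KD·Pch)`, the growing dried-cake resistance
`Rp = R0 + A1·Lck / (1 + A2·Lck)`, and `Psub` the equilibrium vapor pressure
of ice at the sublimation-front temperature `Tsub`. On top of this core the
package provides:

* **Freezing calculator** — 0D lumped-capacitance cooling, crystallization
  hold and solid cooling, plus film-coefficient fitting from thermocouple
  data (`simulate_freezing()`, `crystallization_time()`,
  `fit_film_coefficient()`, `biot_number()`).
* **Primary-drying simulator** — time stepping with arbitrary
  shelf-temperature / chamber-pressure schedules, or classical
  product-length-division stepping (`simulate_primary_drying()`,
  `simulate_primary_drying_by_divisions()`, `quasi_steady_solve()`).
* **Calibration modes** — `Kv` from an experimental drying time,
  `(Kc, Kp, KD)` from multi-pressure calibrations, and the `Rp(Lck)` curve
  from a measured product-temperature trace (`fit_kv_to_drying_time()`,
  `fit_kv_pressure_curve()`, `rp_profile_from_temperature()`,
  `fit_rp_curve()`).
* **Design-space generator** — flux maps over `(Pch, Tsh)` with the critical
  product-temperature limit curve and the equipment-capability line
  `ṁ = a + b·Pch` (`generate_design_space()`, `product_limit_trajectory()`,
  `optimal_setpoint()`).
* **Per-time-step optimizer** — variable `Pch(t)` and/or `Tsh(t)` profiles
  maximizing sublimation flux under product-temperature, shelf-temperature,
  pressure and equipment constraints (`optimize_cycle()`,
  `optimize_step()`).

A small parameter library of published vial geometries, cake-resistance
coefficients and heat-transfer coefficients ships under `inst/extdata/`
(`lyo_library()`), a YAML config loader with mandatory unit suffixes under
`load_config()`, and a thin CLI under `inst/cli/lyodry`.

## Worked example

The laboratory benchmark system: 2 mL of 5% mannitol in Schott 6R vials,
398 vials on one shelf.

```r
library(lyodry)
vial <- vial_from_library("Schott 6R")
mann <- formulation_from_library("5% mannitol")
htm  <- heat_transfer_from_library("Schott 6R")

# typical constant-setpoint cycle: 150 mTorr, shelf ramped -5 -> 30 degC
cfg <- drying_config(vial, mann, htm, vfill = 2,
                     shelf = lyo_schedule(-5, targets = 30, rates = 1,
                                          holds = 48),
                     pressure = 0.15, n_vials = 398)
simulate_primary_drying(cfg)
#> Primary drying: 5.443 h (Lpr0 = 0.6916 cm, max Tbot = -12.80 degC,
#>                          mean Tbot = -17.39 degC)

# per-step optimization of both setpoints under Tpr,max = -5 degC
cfg30 <- drying_config(vial, mann, htm, vfill = 2, shelf = 30,
                       pressure = 0.15, n_vials = 398)
best <- optimize_cycle(cfg30, optimizer_constraints(t_pr_max = -5))
best
#> Primary drying: 2.025 h (Lpr0 = 0.6916 cm, max Tbot = -5.00 degC,
#>                          mean Tbot = -5.00 degC)
table(best$profile$binding)
#> Tpr-max Tsh-max
#>      39       2
```

The typical cycle keeps the product 12–30 °C below its −5 °C limit and
takes 5.44 h; re-optimizing the chamber pressure and shelf temperature every
3 min rides the product-temperature constraint the whole way (binding tag
`Tpr-max`) and finishes in 2.03 h — a 63% reduction. Calibration works the
same way in reverse: fitting `Kv` to the measured 11.62 h drying time at
300 mTorr returns `5.319e-04 cal/(s K cm2)`.

The drying physics, parameter meanings, numerical choices and validation
strategy are documented in `vignettes/freeze-drying-model.Rmd`.

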