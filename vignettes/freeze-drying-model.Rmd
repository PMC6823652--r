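---
title: "Modeling and optimizing vial freeze-drying with lyodry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing vial freeze-drying with lyodry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyodry)
```

## The process and the models

Lyophilization stabilizes drug and biologic formulations by freezing the
filled vials on a temperature-controlled shelf and then subliming the ice
under vacuum (primary drying). Primary drying is by far the longest and most
expensive step, and its two control inputs — chamber pressure $P_{ch}$ and
shelf temperature $T_{sh}$ — are traditionally held at conservative constant
setpoints. `lyodry` implements the chain of models needed to do better: a
freezing calculator, a primary-drying simulator, calibration modes for the
two empirical transport parameters, a Quality-by-Design design-space
generator, and a per-time-step setpoint optimizer.

### Freezing: 0D lumped capacitance

The product is treated as a single thermal mass exchanging heat with the
shelf only:

$$\rho C_p V \frac{dT_{pr}}{dt} = -h A_v \left(T_{pr} - T_{sh}(t)\right).$$

Cooling proceeds with liquid properties until the (user-supplied)
nucleation temperature $T_n$ is reached; the temperature then jumps to the
equilibrium freezing point $T_f$ and stays there while the latent-heat
budget $\rho V \left(H_f - C_p (T_f - T_n)\right)$ is removed; solid
cooling follows with ice properties. For a constant shelf this reduces to a
closed-form crystallization time, which the integrator reproduces to one
time step (a tested invariant). Under a ramping shelf the hold is computed
by integrating the instantaneous heat removal — the natural generalization,
exact in the constant-shelf limit.

Assumptions worth stating plainly: heat enters through the shelf only (no
ambient or radiative paths), nucleation is not modeled stochastically
($T_n$, $T_f$ are inputs, as they must be measured), and the lumped
approximation is marginal during liquid cooling of watery fills (Biot
number around 0.6 against the usual 0.1 cut-off; `biot_number()` warns).
The freezing results are therefore cycle-design aids, not precision
predictions; crystallization times in particular are overpredicted relative
to thermocouple data.

### Primary drying: 1D quasi-steady front

At each instant the dried cake (length $L_{ck}$) sits above the receding
frozen layer ($L_{pr} = L_{pr,0} - L_{ck}$) and three transport legs must
carry the same heat flow:

$$\dot Q = (T_{sh} - T_{bot})\,K_v A_v
        = \frac{(T_{bot} - T_{sub})\,A_p k_{ice}}{L_{pr}}
        = \frac{(P_{sub} - P_{ch})\,A_p\,\Delta H_s}{R_p},$$

with the vial heat-transfer coefficient
$K_v = K_c + K_p P_{ch} / (1 + K_D P_{ch})$, the cake resistance
$R_p = R_0 + A_1 L_{ck}/(1 + A_2 L_{ck})$, and $P_{sub}$ the equilibrium
vapor pressure at the front temperature $T_{sub}$. Eliminating $T_{bot}$
through the conduction leg leaves one scalar equation in $T_{sub}$, solved
by safeguarded bracketed root finding (`uniroot` on
$[T_{sh} - 200, T_{sh}]$ °C, tolerance $10^{-12}$); the three legs agree to
better than $10^{-9}$ relative at every accepted step, which the test suite
asserts along full runs. The front advances by
$dL_{ck} = \dot m'' \, dt / \rho_{ice}$, consistent with the ice-density
basis of the initial frozen length

$$L_{pr,0} = \frac{V_{fill}}{A_p \rho_{ice}}\left(\rho_{solution} -
  \frac{c_{solid}(\rho_{solution} - \rho_{ice})}{\rho_{solute}}\right),$$

so the integrated sublimed mass equals $\rho_{ice} A_p L_{pr,0}$ exactly
(mass conservation is a tested invariant). Drying ends when
$L_{ck} = L_{pr,0}$, with the final partial step linearly interpolated.

Two stepping schemes are provided. Time stepping (default
$\Delta t = 0.05$ h, i.e. 3 min) is the primary mode and supports
time-varying setpoint schedules. Product-length division stepping —
dividing $L_{pr,0}$ into $n$ equal increments and holding the flux constant
across each — is the scheme common to older calculators; it is included
for convergence studies, since coarse divisions systematically
underestimate long cycles (for a ~120 h cycle, going from 10 to 100
divisions lengthens the computed time by several hours).

## Empirical parameters and their calibration

$K_v$ and $R_p$ are the two empirical inputs. When unknown:

* `fit_kv_to_drying_time()` exploits the strict monotonicity of drying
  time in $K_v$ and bisects (in log $K_v$, bracket
  $[10^{-5}, 10^{-2}]$ cal s⁻¹K⁻¹cm⁻², time tolerance $10^{-3}$ h) until
  the simulated time matches an experimental drying time, e.g. from
  Pirani/capacitance-manometer convergence.
* `fit_kv_pressure_curve()` turns three or more $(P_{ch}, K_v)$ pairs into
  $(K_c, K_p, K_D)$ by bounded Levenberg–Marquardt least squares
  (`minpack.lm`); three distinct pressures determine the curve exactly.
* `rp_profile_from_temperature()` inverts the three-leg balance sample by
  sample along a measured $T_{bot}(t)$ trace, advancing $L_{ck}$ with the
  running flux integral so the extraction is self-consistent, and
  `fit_rp_curve()` fits $(R_0, A_1, A_2)$ under nonnegativity constraints.

All four calibrations are validated as round trips through the forward
model: simulate with known parameters, recover them from the simulated
"measurements" (noiseless to $10^{-8}$–$10^{-3}$ depending on the chain;
within 10% under seeded Gaussian thermocouple noise of 0.2–0.3 °C).

## Design space and the per-step optimizer

`generate_design_space()` maps sublimation flux over a $(P_{ch}, T_{sh})$
grid at a chosen drying stage, together with the critical
product-temperature limit curve — obtained by pinning $T_{bot}$ at
$T_{pr,max}$, solving the two product-side legs for the front state, and
backing the required $T_{sh}$ out of the vial leg — and the equipment
capability line $\dot m_{eq\,cap} = a + b P_{ch}$, whose coefficients
(from choked-flow tests or CFD) are inputs. The conventional constant
setpoint is the intersection of the limit curve with the capability line
(`optimal_setpoint()`); built at end-of-drying resistance it is
conservative for the whole cycle, a property spot-checked by simulation in
the tests.

Because $R_p$ grows during drying, the best setpoint drifts, and a constant
choice wastes most of the cycle. `optimize_cycle()` instead re-optimizes
every control interval (default 3 min): for each candidate pressure the
shelf temperature is the lower of its ceiling and the value pinning
$T_{bot}$ at $T_{pr,max}$; if the batch rate $n_{vials}\,\dot m''A_p$
would exceed the capability line, the flux is held on the line and the
state backed out at that flux. The pressure maximizing the resulting flux
is found by a 41-point log-spaced scan refined by golden-section search,
with ties resolved to the lower pressure (cheaper vacuum). Each step
reports which constraint binds; on a capability-limited batch the tag
sequence shows the expected handover from equipment-bound to
product-temperature-bound as resistance builds. Single-variable modes hold
the other input on its schedule. The optimizer's flux-maximality is tested
against an exhaustive 400×200 grid scan, and its drying time against a
feasible constant-setpoint grid (dominance).

With the bottom pinned at $T_{pr,max}$ and pressure fixed, the required
shelf temperature *falls* as drying proceeds: flux decays roughly with
$1/R_p$, so the heat demand shrinks faster than the driving-force algebra
grows. This is the falling $T_{sh}$ profile seen in
product-temperature-limited optimized cycles, and the direction the
package asserts in its tests.

## Numerical and physical choices

* **Units.** All internal computation is in the practical system of the
  field's tables — cal, g, cm, Torr, hours, °C — with `convert_units()`
  at the boundaries. This makes every intermediate directly comparable to
  printed values and confines unit risk to I/O, where the config format
  demands explicit unit suffixes on every key.
* **Ice vapor pressure.** $P_{sub}(T) = 2.698\times10^{10}
  e^{-6144.96/T}$ Torr ($T$ in K), the correlation standard in
  primary-drying models; it reproduces the triple-point pressure within
  1%. The coefficients are exposed in `lyo_constants()` and can be
  swapped.
* **Material constants.** $\Delta H_s = 678$ cal/g,
  $k_{ice} = 0.0059$ cal s⁻¹cm⁻¹K⁻¹, $H_f = 79.7$ cal/g,
  $C_{p,liq} = 1.0$ and $C_{p,ice} = 0.503$ cal g⁻¹K⁻¹,
  $\rho_{ice} = 0.918$ g/cm³ — handbook values used throughout the
  freeze-drying modeling literature, all overridable. Temperature
  dependence of $k_{ice}$, $\Delta H_s$ and $C_p$ is neglected. Benchmark
  drying times are sensitive at the few-percent level to the exact
  constant set (reference implementations rarely publish theirs), which
  is why the validation suite checks drying times to 5–10% rather than
  to printed precision; the acceptance comparisons in the shipped tests
  sit within those bands with a small systematic offset of a few
  percent.
* **Areas.** $A_v$ (shelf heat transfer) from the outer diameter, $A_p$
  (product cross-section) from the inner diameter, consistent with the
  vial heat-transfer literature.
* **Degenerate inputs.** When the front vapor pressure cannot exceed the
  chamber pressure the solver returns the zero-flux equilibrium state
  rather than failing; a vanishing frozen layer ($L_{pr} < 10^{-9}$ cm)
  sets $T_{bot} = T_{sub}$ analytically; $A_2 = 0$ resistance entries are
  honored as exactly linear growth.
* **Schedules.** Setpoint schedules are piecewise-linear
  (target / ramp-rate / hold segments, rates in units per minute), extend
  their final value indefinitely, and accept bare numbers as constants.
  The benchmark "typical cycle" ramps the shelf from the −5 °C
  freezing-stage value to 30 °C at 1 °C/min, the laboratory ramp rate;
  optimized cycles assume setpoints are reachable within one control
  interval.
* **Sucrose benchmark fill.** The published sucrose comparison is
  ambiguous about the fill volume (1 vs 2 mL in different places); the
  package's benchmark uses 2 mL and checks the formulation-level claim —
  a ≈50% drying-time reduction from variable-setpoint optimization — not
  absolute hours.

## What the synthetic-data generator does and does not emulate

`generate_synthetic_profile()` produces thermocouple-like traces by
forward simulation plus seeded additive Gaussian noise (σ of a few tenths
of a °C, the scale of thermocouple scatter). It emulates sampling density
and sensor noise; it does **not** emulate model error — edge-vial
radiation, stochastic nucleation, thermocouple bias from the probe's own
heat conduction, shelf-surface temperature fluctuation, or Pirani endpoint
ambiguity. Calibration tests passing on these fixtures therefore
demonstrate that the inverse modes are algebraically correct and
noise-stable, not that they are unbiased on real laboratory data.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the laboratory-scale
benchmark cases directly: 2 mL fills of 5% mannitol (≈250 time steps at
the default 3-min step for the slowest constant cycle, ≈40–110 optimizer
steps for the optimized ones), the 8 mL slow cycle with 10/100 length
divisions, and a 36–38 h sucrose cycle. The brute-force cross-checks
(bisection oracles, exhaustive setpoint scans, 5×5 constant-setpoint
grids) are sized to finish in seconds while still bracketing the optima
well inside the asserted tolerances.

## Known limitations

Single representative center vial (no edge-effect heterogeneity, which the
field handles by splitting the batch into vial classes with separate
$K_v$); no secondary drying; no condenser or duct dynamics beyond the
capability line; no stochastic nucleation; no choked-flow computation of
the capability coefficients; freezing accuracy limited by the 0D
assumption. These match the stated scope of the modeling approach the
package implements.

## A worked example

```{r, eval = FALSE}
vial <- vial_from_library("Schott 6R")
mann <- formulation_from_library("5% mannitol")
htm  <- heat_transfer_from_library("Schott 6R")

cfg <- drying_config(vial, mann, htm, vfill = 2,
                     shelf = lyo_schedule(-5, targets = 30, rates = 1,
                                          holds = 48),
                     pressure = 0.15, n_vials = 398)
typical <- simulate_primary_drying(cfg)
typical$drying_time        # ~5.4 h

cfg30 <- drying_config(vial, mann, htm, vfill = 2, shelf = 30,
                       pressure = 0.15, n_vials = 398)
best <- optimize_cycle(cfg30, optimizer_constraints(t_pr_max = -5))
best$drying_time           # ~2.0 h: ~63% faster than the typical cycle
table(best$profile$binding)
```
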