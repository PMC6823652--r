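# Shared fixtures: the 2 mL 5% mannitol / Schott 6R laboratory case and an
# independent brute-force oracle for the quasi-steady balance.

mannitol_formulation <- function()
  formulation(0.05, r0 = 1.4, a1 = 16, a2 = 0, t_pr_max = -5,
              rho_solute = 1.52, name = "5% mannitol")

sucrose_formulation <- function()
  formulation(0.05, r0 = 0.208, a1 = 15.29, a2 = 1.6, t_pr_max = -35,
              rho_solute = 1.587, name = "5% sucrose")

vial_6r <- function() vial_geometry(22, 20, name = "Schott 6R")

htm_6r <- function() heat_transfer_model(kc = 2.75e-4, kp = 8.93e-4,
                                         kd = 0.46)

mannitol_6r_config <- function(shelf = -5, pressure = 0.3, vfill = 2,
                               htm = htm_6r(), n_vials = 1L, dt = 0.05) {
  drying_config(vial_6r(), mannitol_formulation(), htm, vfill, shelf,
                pressure, n_vials = n_vials, dt = dt)
}

# Brute-force bisection oracle for the coupled heat/mass balance, written
# directly from the constitutive relations and independent of the package's
# solver. 200 bisections pin the front temperature to machine precision.
oracle_quasi_steady <- function(tsh, pch, lck, lpr0, kv, av, ap,
                                r0 = 1.4, a1 = 16, a2 = 0,
                                dhs = 678, kice = 0.0059) {
  rp <- r0 + a1 * lck / (1 + a2 * lck)
  psub <- function(ts) 2.698e10 * exp(-6144.96 / (ts + 273.15))
  resid <- function(ts) {
    fl <- (psub(ts) - pch) / rp
    tb <- ts + fl * dhs * (lpr0 - lck) / (kice * 3600)
    (tsh - tb) * kv * 3600 * av - fl * dhs * ap
  }
  lo <- tsh - 150
  hi <- tsh
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(resid(mid)) == sign(resid(lo))) lo <- mid else hi <- mid
  }
  ts <- (lo + hi) / 2
  fl <- (psub(ts) - pch) / rp
  list(t_sub = ts, flux = fl,
       t_bot = ts + fl * dhs * (lpr0 - lck) / (kice * 3600))
}

# relative deviation helper
rel_dev <- function(x, ref) abs(x - ref) / abs(ref)
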