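#' Parameter library of vials, products and heat-transfer coefficients
#'
#' The package ships a small human-editable library (CSV files under
#' `extdata/`) of published vial geometries, formulation cake-resistance
#' coefficients and vial heat-transfer coefficients, keyed by name. Units
#' are recorded in the column headers.
#'
#' @param which One of `"products"`, `"vials"`, `"heat_transfer"`.
#' @return The library table as a data frame.
#' @export
#' @examples
#' lyo_library("vials")
lyo_library <- function(which = c("products", "vials", "heat_transfer")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "lyodry")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.library_row <- function(which, name) {
  tab <- lyo_library(which)
  hit <- tab[tab$name == name, , drop = FALSE]
  if (nrow(hit) != 1)
    stop("no unique entry '", name, "' in the ", which, " library; ",
         "available: ", paste(tab$name, collapse = ", "))
  as.list(hit)
}

#' Look up a vial geometry by name
#' @param name Library key, e.g. `"Schott 6R"`.
#' @return A [vial_geometry()].
#' @export
vial_from_library <- function(name) {
  r <- .library_row("vials", name)
  vial_geometry(r$outer_diameter_mm, r$inner_diameter_mm, name = name)
}

#' Look up a formulation by name
#' @param name Library key, e.g. `"5% mannitol"`.
#' @return A [formulation()].
#' @export
formulation_from_library <- function(name) {
  r <- .library_row("products", name)
  formulation(csolid = r$csolid_g_mL, r0 = r$r0_cm2_h_Torr_g,
              a1 = r$a1_cm_h_Torr_g, a2 = r$a2_per_cm,
              t_pr_max = r$t_pr_max_C, rho_solution = r$rho_solution_g_cm3,
              rho_solute = r$rho_solute_g_cm3, name = name)
}

#' Look up a vial/lyophilizer heat-transfer model by name
#' @param name Library key, e.g. `"Schott 6R"`.
#' @return A [heat_transfer_model()].
#' @export
heat_transfer_from_library <- function(name) {
  r <- .library_row("heat_transfer", name)
  if (!is.na(r$fixed_kv_cal_s_K_cm2) && r$fixed_kv_cal_s_K_cm2 != "")
    return(heat_transfer_model(fixed_kv = as.numeric(r$fixed_kv_cal_s_K_cm2),
                               name = name))
  heat_transfer_model(kc = as.numeric(r$kc_cal_s_K_cm2),
                      kp = as.numeric(r$kp_cal_s_K_cm2_Torr),
                      kd = as.numeric(r$kd_per_Torr), name = name)
}

# ---- run configuration ------------------------------------------------------

.known_modes <- c("freeze", "dry", "dry-by-divisions", "fit-kv",
                  "fit-kv-curve", "fit-rp", "design-space", "optimize")

# schedule from a config entry: a bare number (constant) or a mapping with
# initial / targets / rates_per_min / holds_h, or times_h / values
.schedule_from_config <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) return(schedule_constant(x))
  if (is.list(x)) {
    if (!is.null(x$times_h))
      return(schedule_table(unlist(x$times_h), unlist(x$values)))
    if (is.null(x$initial))
      stop("schedule '", what, "' needs 'initial' (or 'times_h'/'values')")
    return(lyo_schedule(x$initial,
                        targets = unlist(x$targets %||% numeric()),
                        rates = unlist(x$rates_per_min %||% 1),
                        holds = unlist(x$holds_h %||% 0)))
  }
  stop("cannot interpret schedule '", what, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration file
#'
#' Reads a YAML configuration describing a run: the mode, the vial, product
#' and heat-transfer model (library names or inline parameter mappings),
#' fill and load, schedules and the optimizer constraint block. Physical
#' quantities carry explicit unit suffixes in their key names (`_mL`, `_C`,
#' `_Torr`, `_h`); unknown top-level keys are rejected loudly, the main
#' defense in a domain whose literature mixes unit systems silently.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `mode`, `config` (a
#'   [drying_config()]), and when present `constraints`
#'   ([optimizer_constraints()]), `n_divisions`, `t_exp_h`, `seed`, `out`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("mode", "vial", "product", "heat_transfer", "vfill_mL",
             "n_vials", "dt_h", "shelf_C", "pressure_Torr", "optimizer",
             "n_divisions", "t_exp_h", "seed", "out", "constants",
             "freezing")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (physical quantities need explicit unit suffixes, e.g. vfill_mL)")
  mode <- raw$mode %||% "dry"
  if (!mode %in% .known_modes)
    stop("unknown mode '", mode, "'; one of: ",
         paste(.known_modes, collapse = ", "))

  as_vial <- function(x) {
    if (is.character(x)) return(vial_from_library(x))
    vial_geometry(x$outer_diameter_mm, x$inner_diameter_mm)
  }
  as_form <- function(x) {
    if (is.character(x)) return(formulation_from_library(x))
    formulation(csolid = x$csolid_g_mL, r0 = x$r0_cm2_h_Torr_g,
                a1 = x$a1_cm_h_Torr_g %||% 0, a2 = x$a2_per_cm %||% 0,
                t_pr_max = x$t_pr_max_C %||% -5,
                rho_solution = x$rho_solution_g_cm3 %||% 1.0,
                rho_solute = x$rho_solute_g_cm3 %||% 1.52)
  }
  as_htm <- function(x) {
    if (is.character(x)) return(heat_transfer_from_library(x))
    if (!is.null(x$fixed_kv_cal_s_K_cm2))
      return(heat_transfer_model(fixed_kv = x$fixed_kv_cal_s_K_cm2))
    heat_transfer_model(kc = x$kc_cal_s_K_cm2, kp = x$kp_cal_s_K_cm2_Torr,
                        kd = x$kd_per_Torr)
  }
  const <- if (is.null(raw$constants)) lyo_constants() else
    do.call(lyo_constants, raw$constants)

  # freeze mode needs only the vial, fill, shelf schedule and the measured
  # freezing characteristics; no drying machinery
  if (mode == "freeze") {
    fz <- raw$freezing
    if (is.null(fz))
      stop("mode 'freeze' requires a 'freezing' block (h_cal_s_K_cm2, ",
           "t_n_C, t_f_C, ...)")
    vial <- as_vial(raw$vial)
    inp <- freezing_inputs(
      v = raw$vfill_mL, av = vial$av,
      h = fz$h_cal_s_K_cm2 %||% 1e-4, t_n = fz$t_n_C,
      t_f = fz$t_f_C %||% 0, t0 = fz$t0_C,
      rho = fz$rho_g_cm3 %||% 1.0,
      cp_liquid = fz$cp_liquid_cal_g_K %||% const$cp_liquid,
      cp_ice = fz$cp_ice_cal_g_K %||% const$cp_ice,
      hf = fz$hf_cal_g %||% const$hf)
    return(structure(list(
      mode = mode, freezing = inp,
      shelf = .schedule_from_config(raw$shelf_C, "shelf_C"),
      dt = raw$dt_h %||% 1e-3, seed = raw$seed, out = raw$out),
      class = "run_config"))
  }

  cfg <- drying_config(
    vial = as_vial(raw$vial), form = as_form(raw$product),
    htm = as_htm(raw$heat_transfer), vfill = raw$vfill_mL,
    shelf = .schedule_from_config(raw$shelf_C, "shelf_C"),
    pressure = .schedule_from_config(raw$pressure_Torr, "pressure_Torr"),
    n_vials = raw$n_vials %||% 1L, dt = raw$dt_h %||% 0.05,
    constants = const)

  cons <- NULL
  if (!is.null(raw$optimizer)) {
    o <- raw$optimizer
    cap <- if (is.null(o$capability)) equipment_capability(disabled = TRUE)
      else equipment_capability(a = o$capability$a_kg_h %||% 0,
                                b = o$capability$b_kg_h_Torr %||% 0)
    cons <- optimizer_constraints(
      t_pr_max = o$t_pr_max_C %||% cfg$form$t_pr_max,
      tsh_min = o$tsh_min_C %||% -60, tsh_max = o$tsh_max_C %||% 120,
      pch_min = o$pch_min_Torr %||% 0.05, pch_max = o$pch_max_Torr %||% 1,
      cap = cap, mode = o$mode %||% "both",
      control_interval = o$control_interval_h %||% 0.05)
  }
  structure(list(mode = mode, config = cfg, constraints = cons,
                 n_divisions = raw$n_divisions, t_exp_h = raw$t_exp_h,
                 seed = raw$seed, out = raw$out),
            class = "run_config")
}

# ---- time series CSV i/o ----------------------------------------------------

#' Write a drying or freezing time series to CSV
#'
#' Fixed column order with units in the header names; values round-trip
#' through [read_timeseries_csv()] losslessly.
#'
#' @param series A `drying_series`, `optimized_cycle`, `freezing_result`, or
#'   a plain data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  df <- if (is.data.frame(series)) series else series$profile
  if (is.null(df) || nrow(df) == 0) stop("empty series: nothing to write")
  rename <- c(t = "time_h", lck = "Lck_cm", t_sub = "Tsub_C",
              t_bot = "Tbot_C", p_sub = "Psub_Torr", flux = "flux_g_cm2_h",
              tsh = "Tsh_C", pch = "Pch_Torr", t_pr = "Tpr_C",
              stage = "stage", pch_opt = "Pch_opt_Torr",
              tsh_opt = "Tsh_opt_C", binding = "binding_constraint")
  nm <- names(df)
  names(df) <- ifelse(nm %in% names(rename), rename[nm], nm)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series CSV written by [write_timeseries_csv()]
#' @param path File path.
#' @return Data frame with the package's internal column names.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rename <- c(time_h = "t", Lck_cm = "lck", Tsub_C = "t_sub",
              Tbot_C = "t_bot", Psub_Torr = "p_sub", flux_g_cm2_h = "flux",
              Tsh_C = "tsh", Pch_Torr = "pch", Tpr_C = "t_pr",
              stage = "stage", Pch_opt_Torr = "pch_opt",
              Tsh_opt_C = "tsh_opt", binding_constraint = "binding")
  nm <- names(df)
  names(df) <- ifelse(nm %in% names(rename), rename[nm], nm)
  df
}

#' Generate a synthetic measured temperature profile
#'
#' Forward-simulates a product-temperature trace (vial-bottom temperature
#' during primary drying, or product temperature during freezing) and adds
#' seeded Gaussian noise, emulating a thermocouple record. Used to exercise
#' the calibration modes without laboratory data.
#'
#' @param truth A [drying_config()] (gives a Tbot trace) or a list
#'   `list(inputs = freezing_inputs, shelf = schedule)` (gives a freezing
#'   Tpr trace).
#' @param noise_sd Gaussian noise standard deviation (degC); 0 returns the
#'   noiseless simulation.
#' @param seed Integer seed; identical seeds give identical series.
#' @param every Keep every `every`-th simulated step.
#' @return Data frame (t, t_bot) or (t, t_pr).
#' @export
generate_synthetic_profile <- function(truth, noise_sd = 0, seed = 1L,
                                       every = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(truth, "drying_config")) {
    prof <- simulate_primary_drying(truth)$profile
    df <- data.frame(t = prof$t, t_bot = prof$t_bot)
    col <- "t_bot"
  } else if (is.list(truth) && inherits(truth$inputs, "freezing_inputs")) {
    prof <- simulate_freezing(truth$inputs, truth$shelf,
                              dt = truth$dt %||% 1e-3)$profile
    df <- data.frame(t = prof$t, t_pr = prof$t_pr)
    col <- "t_pr"
  } else stop("truth must be a drying_config or list(inputs=, shelf=)")
  df <- df[seq(1, nrow(df), by = every), , drop = FALSE]
  rownames(df) <- NULL
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    df[[col]] <- df[[col]] + stats::rnorm(nrow(df), sd = noise_sd)
  }
  df
}
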