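#' Default model configuration
#'
#' Assembles the full parameter set of the simulator as a nested list:
#' physical constants of the fluid and particle phases, reaction and
#' dissolution kinetics, secretion/absorption rate constants, tract geometry,
#' peristaltic wave and pyloric gate parameters, and numerics. Every value can
#' be overridden either by passing a replacement sub-list through `...` or by
#' editing a configuration file written with [write_config()].
#'
#' Secretion constants are stored as regional totals in kg/s (the tabulated
#' per-volume constants are defined as total/V(l), so the wall-layer volume
#' V(l) cancels from all regional budgets; it is derived from the geometry and
#' only fixes the local per-m^3 source intensity).
#'
#' @param ... named replacements merged (recursively) over the defaults, e.g.
#'   `gi_config(numerics = list(dx = 4e-3))`.
#' @return A nested list of class `gi_config`.
#' @export
#' @examples
#' cfg <- gi_config(numerics = list(dx = 4e-3))
#' cfg$numerics$dx
gi_config <- function(...) {
  cfg <- list(
    fluid = list(rho = 1000, eta = 1e-3),
    particle = list(
      density = 1040, viscosity = 1,
      diameters = c(3.6, 2.8, 1.7, 0.7, 0.2) * 1e-3,
      beta = c(protein = 0.013, fat = 0.001, carbohydrate = 0.093 - 0.28e-6,
               chemical = 0.28e-6, water = 0.893)
    ),
    reaction = list(
      k02 = 1e4,            # m^3/(kmol s), acid-bicarbonate neutralization
      k37 = 0.038,          # 1/s, proteolysis turnover
      k37_prime = 1.4e-3,   # kmol/m^3, proteolysis half-saturation
      a37 = -5.786, b37 = 26.819, c37 = -4.857  # pepsin pH modifier
    ),
    dissolution = list(
      k_phys = 2.72e-4,     # kg/(m^2 s) at the reference gastric pH
      a = 3.246, b = -2.092, # k = k_phys * a * pH^b
      ph_cut = 7            # no dissolution at neutral/alkaline pH
    ),
    ph = list(c_floor = 1e-8),  # kmol/m^3; caps reported pH at 8
    secretion = list(
      acid = list(basal = 0.404e-7, protein = 1.616e-7, fat = 1.315e-7,
                  carbohydrate = 1.54e-7, half_sat = 12.66, water = 171.3),
      pepsin = list(basal = 0.416e-8, max = 1.664e-8, half_sat = 12.66),
      bicarbonate = list(
        r3 = list(basal = 1.75e-8, max = 7e-8, half_sat = 0.5, water = 395.5),
        r4 = list(basal = 0.278e-8, max = 1.112e-8, half_sat = 0.5, water = 395.5),
        r5 = list(basal = 1.972e-7, max = 7.888e-7, half_sat = 0.5, water = 78.3)
      )
    ),
    absorption = list(rate = 3.34e-3, h = 1, blood_conc = 0, layer_frac = 0.1),
    geometry = list(
      antrum_length = 0.10, antrum_r_max = 0.022, antrum_r_end = 0.006,
      pylorus_length = 0.01, pylorus_radius = 0.004,
      duodenum_length = 0.18, duodenum_radius = 0.010,
      fill_end = 0.07, region2_end = 0.06,
      region4_end = 0.07, region5_end = 0.13,  # lengths past the pylorus exit
      gravity_antrum = -0.5, gravity_duodenum = 0.3, g = 9.81,
      r_floor = 2e-3
    ),
    waves = list(
      antral = list(period = 18, width = 0.02, amplitude = 0.009,
                    speed = 0.0022, duration = 38, origin = 0),
      duodenal = list(period = 9, width = 0.04, amplitude = 0.0035,
                      speed = 0.005, duration = 36),
      ramp = 2  # s, linear amplitude envelope at wave birth/death
    ),
    gate = list(period = 18, open_duration = 2, phase = NULL),
    numerics = list(
      dx = 2e-3, cfl = 0.4, dt_max = 0.05, diffusion = TRUE,
      advection_order = 2,  # MUSCL/minmod reconstruction; 1 = plain upwind
      clip_tol = 1e-6, max_substeps = 2e6,
      slip_tol = 1e-10, slip_maxit = 100, slip_cap = 0.2,
      tau_relax = 0.5
    ),
    output = list(dt = 1, ph_every = 50)
  )
  cfg <- modify_list_deep(cfg, list(...))
  class(cfg) <- "gi_config"
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Write / read a configuration file
#'
#' The full configuration round-trips through a plain-text YAML file; any key
#' may be edited before reloading. Reading merges the file over the package
#' defaults, so partial files are valid.
#'
#' @param config a `gi_config` list.
#' @param path file path.
#' @return `read_config` returns a `gi_config`; `write_config` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gi_config"))
  # emit doubles with 17 significant digits so reloading is bit-identical
  num_handler <- function(y) {
    r <- sprintf("%.17g", y)
    whole <- !grepl("[.eE]", r) & is.finite(y)
    r[whole] <- paste0(r[whole], ".0")   # keep doubles typed as doubles
    class(r) <- "verbatim"
    r
  }
  yaml::write_yaml(unclass(config), path,
                   handlers = list(numeric = num_handler))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml reads numeric vectors as lists; flatten pure-numeric lists
  flatten <- function(x) {
    if (is.list(x)) {
      if (length(x) && all(vapply(x, function(e) is.numeric(e) && length(e) == 1L, TRUE)) &&
          is.null(names(x))) {
        return(unlist(x))
      }
      return(lapply(x, flatten))
    }
    x
  }
  cfg <- modify_list_deep(unclass(gi_config()), flatten(raw))
  class(cfg) <- "gi_config"
  cfg
}

#' Secretion unit-conversion derivations
#'
#' Helpers that reproduce how the secretion constants are obtained from
#' physiological rates: a molar gland output is converted to a mass rate, the
#' water co-secretion ratio follows from the acid mass fraction of gastric
#' juice, and the basal rate is a fixed factor below the maximal rate.
#'
#' @param molar_rate gland output in kmol/h (> 0).
#' @param molar_mass kg/kmol (> 0).
#' @return `derive_acid_mass_rate`: the mass rate in kg/s.
#' @export
#' @examples
#' derive_acid_mass_rate(20e-6, 36.46)   # ~2.03e-7 kg/s
#' derive_water_coupling(0.0058)         # ~171.4
#' derive_basal_rate(2.02e-7, 5)
derive_acid_mass_rate <- function(molar_rate, molar_mass) {
  if (any(molar_rate <= 0) || any(molar_mass <= 0)) {
    stop("molar rate and molar mass must be positive")
  }
  molar_rate * molar_mass / 3600
}

#' @rdname derive_acid_mass_rate
#' @param acid_mass_fraction mass fraction w of acid in the secreted fluid,
#'   0 < w < 1.
#' @return `derive_water_coupling`: the water:acid mass-rate ratio (1 - w)/w.
#' @export
derive_water_coupling <- function(acid_mass_fraction) {
  if (any(acid_mass_fraction <= 0) || any(acid_mass_fraction >= 1)) {
    stop("acid mass fraction must lie strictly between 0 and 1")
  }
  (1 - acid_mass_fraction) / acid_mass_fraction
}

#' @rdname derive_acid_mass_rate
#' @param maximal_rate stimulated secretion rate, kg/s.
#' @param factor basal-to-maximal ratio denominator (> 0), default 5.
#' @return `derive_basal_rate`: maximal_rate / factor in kg/s.
#' @export
derive_basal_rate <- function(maximal_rate, factor = 5) {
  if (any(factor <= 0)) stop("factor must be positive")
  maximal_rate / factor
}

#' Functional-disorder scenarios
#'
#' Six built-in scenarios: (1) baseline, no disorders, particle density
#' 1040 kg/m^3; (2, 3) reduced acid secretion in the upper antrum,
#' F(2)(1) = 0.5 and 0.2 (atrophic gastritis of increasing severity);
#' (4, 5) reduced alkaline secretion in all bicarbonate regions,
#' F(l)(1) = 0.5 and 0.2 for l = 3..5 (duodenal ulcer / pancreatic
#' insufficiency); (6) baseline functionality with light particles
#' (1005 kg/m^3).
#'
#' @param id integer scenario number, 1..6.
#' @return A list with `id`, the 4x3 functionality matrix `F` (regions 2..5 x
#'   secretion/absorption/motor) and `particle_density` (kg/m^3).
#' @export
#' @examples
#' load_scenario(3)$F
load_scenario <- function(id) {
  if (length(id) != 1L || is.na(id) || !(id %in% 1:6)) {
    stop("unknown scenario id: must be an integer in 1..6", call. = FALSE)
  }
  id <- as.integer(id)
  F21 <- c(1, 0.5, 0.2, 1, 1, 1)[id]
  Falk <- c(1, 1, 1, 0.5, 0.2, 1)[id]
  dens <- c(1040, 1040, 1040, 1040, 1040, 1005)[id]
  Fm <- functionality_map(
    secretion = c("2" = F21, "3" = Falk, "4" = Falk, "5" = Falk)
  )
  list(id = id, F = Fm, particle_density = dens)
}

#' Consistency checks of the derived secretion constants
#'
#' Recomputes the gland-output conversions from first principles and compares
#' them with the configured defaults: the maximal acid mass rate from
#' 20 mmol/h of HCl, the water:acid coupling from a 0.58% acid mass fraction,
#' the implied water flow, and the basal = maximal/5 relation. Also checks the
#' pepsin pH-modifier landmarks (optimum and upper zero) against a brute-force
#' scan of the quadratic.
#'
#' @param config a `gi_config`.
#' @return A data.frame with columns `check`, `expected`, `actual`,
#'   `rel_error`, `pass`; invisibly TRUE/FALSE overall as attribute "ok".
#' @export
gi_validate <- function(config = gi_config()) {
  reg <- component_registry()
  acid <- derive_acid_mass_rate(20e-6, reg$molar_mass[reg$name == "HCl"])
  water_ratio <- derive_water_coupling(0.0058)
  water_flow <- water_ratio * acid
  basal <- derive_basal_rate(acid, 5)
  sa <- config$secretion$acid
  max_cfg <- sa$basal + sa$protein  # saturated, protein-stimulated

  modifier <- function(ph) {
    pmax(0, config$reaction$a37 * ph^2 + config$reaction$b37 * ph +
           config$reaction$c37)
  }
  grid <- seq(0, 8, by = 1e-4)
  f <- modifier(grid)
  vertex <- grid[which.max(f)]
  pos <- grid[f > 0]
  upper_zero <- if (length(pos)) max(pos) else NA_real_

  rows <- rbind(
    data.frame(check = "maximal acid mass rate (kg/s)",
               expected = 2.02e-7, actual = acid),
    data.frame(check = "configured saturated acid rate (kg/s)",
               expected = acid, actual = max_cfg),
    data.frame(check = "water:acid coupling",
               expected = sa$water, actual = water_ratio),
    data.frame(check = "water co-secretion flow (kg/s)",
               expected = 346e-7, actual = water_flow),
    data.frame(check = "basal acid rate (kg/s)",
               expected = 0.404e-7, actual = basal),
    data.frame(check = "pepsin modifier optimum (pH)",
               expected = 2.32, actual = vertex),
    data.frame(check = "pepsin modifier upper zero (pH)",
               expected = 4.44, actual = upper_zero)
  )
  rows$rel_error <- abs(rows$actual - rows$expected) / abs(rows$expected)
  rows$pass <- rows$rel_error < 0.01
  attr(rows, "ok") <- all(rows$pass)
  rows
}
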