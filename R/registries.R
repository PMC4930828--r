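#' Component registry of the first (fluid) phase
#'
#' The first phase is a ten-component solution. Component ordering is fixed:
#' hydrochloric acid (i = 0), the inert neutralization product (sodium chloride
#' plus carbon dioxide, i = 1), sodium bicarbonate (i = 2), dissolved proteins
#' (i = 3), fats (i = 4), carbohydrates (i = 5), a trace chemical exemplified
#' by lead (i = 6), pepsin (i = 7), polypeptides (i = 8) and water (i = 9).
#'
#' Molar masses are in kg/kmol. The molar mass of the reaction product is the
#' sum of NaCl (58.44) and CO2 (44.01) so that the neutralization
#' NaHCO3 + HCl -> NaCl + CO2 + H2O conserves mass exactly:
#' M0 + M2 = M1 + M9 = 120.47. Proteins use the synthetic dipeptide substrate
#' N-acetyl-L-phenylalanyl-L-phenylalanine (354.4); pepsin 35000. The shared
#' diffusion coefficient of dissolved components is 1e-9 m^2/s.
#'
#' @return A data.frame with columns `index` (0..9), `name`, `molar_mass`
#'   (kg/kmol) and `diffusion` (m^2/s).
#' @export
#' @examples
#' component_registry()
component_registry <- function() {
  df <- data.frame(
    index = 0:9,
    name = c("HCl", "reaction_product", "NaHCO3", "protein", "fat",
             "carbohydrate", "chemical", "pepsin", "polypeptide", "water"),
    molar_mass = c(36.46, 102.45, 84.01, 354.4, 180.16,
                   180.16, 207.2, 35000, 354.4, 18.02),
    diffusion = rep(1e-9, 10),
    stringsAsFactors = FALSE
  )
  df
}

#' Particle-phase registry
#'
#' Phases j = 2..6 are food-particle size bins with fixed representative
#' diameters (mm: 3.6, 2.8, 1.7, 0.7, 0.2). The composition of the particle
#' material follows raw carrot: protein 0.013, fat 0.001, carbohydrate
#' 0.093 - beta6, trace chemical 2.8e-7, water 0.893 (mass fractions summing
#' to one). The smallest bin (j = 6) represents nondigestible fibres and never
#' dissolves. Phase j = 1 is the carrier fluid (density 1000 kg/m^3,
#' viscosity 1e-3 Pa s).
#'
#' @param particle_density density of particle phases, kg/m^3 (1040 in
#'   scenarios 1-5, 1005 in scenario 6).
#' @param particle_viscosity effective shear viscosity of the particle
#'   pseudo-fluid phases, Pa s.
#' @return A data.frame with one row per phase j = 1..6: `phase`, `diameter`
#'   (m, NA for the fluid), `density`, `viscosity`, `dissolvable`, and the
#'   composition columns `beta3`, `beta4`, `beta5`, `beta6`, `beta9`.
#' @export
phase_registry <- function(particle_density = 1040, particle_viscosity = 1) {
  beta6 <- 0.28e-6
  beta5 <- 0.093 - beta6
  data.frame(
    phase = 1:6,
    diameter = c(NA, 3.6, 2.8, 1.7, 0.7, 0.2) * 1e-3,
    density = c(1000, rep(particle_density, 5)),
    viscosity = c(1e-3, rep(particle_viscosity, 5)),
    dissolvable = c(NA, TRUE, TRUE, TRUE, TRUE, FALSE),
    beta3 = c(NA, rep(0.013, 5)),
    beta4 = c(NA, rep(0.001, 5)),
    beta5 = c(NA, rep(beta5, 5)),
    beta6 = c(NA, rep(beta6, 5)),
    beta9 = c(NA, rep(0.893, 5))
  )
}

#' Functionality map of the tract wall regions
#'
#' Each secretory/absorptive wall region l = 2..5 (2: acid-secreting upper
#' antrum wall, 3: bicarbonate-secreting lower antrum, 4: duodenal wall,
#' 5: pancreatic inflow region) carries a functionality F in [0, 1] for each
#' of the three wall functions m = 1 (secretion), 2 (absorption), 3 (motor).
#' F = 1 - D where D is the damage level; F = 1 means no disorder and scales
#' the corresponding source or wave amplitude linearly.
#'
#' @param secretion,absorption,motor either a single value recycled over
#'   regions 2..5 or a named numeric vector with names "2".."5".
#' @return A 4x3 matrix with rownames "2".."5" and colnames
#'   c("secretion", "absorption", "motor").
#' @export
functionality_map <- function(secretion = 1, absorption = 1, motor = 1) {
  expand1 <- function(v, what) {
    if (length(v) == 1L) v <- stats::setNames(rep(v, 4), as.character(2:5))
    v <- v[as.character(2:5)]
    if (anyNA(v)) stop("functionality for ", what, " must cover regions 2..5")
    if (any(v < 0 | v > 1)) stop("functionality must lie in [0, 1]")
    v
  }
  m <- cbind(secretion = expand1(secretion, "secretion"),
             absorption = expand1(absorption, "absorption"),
             motor = expand1(motor, "motor"))
  rownames(m) <- as.character(2:5)
  m
}
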