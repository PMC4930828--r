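#' Molar concentration of a dissolved component
#'
#' C_i = alpha1 * Y_i * rho1 / M_i, in kmol/m^3 of mixture (equivalently
#' mol/L, so pH needs no unit conversion).
#'
#' @param alpha1 fluid-phase volume fraction.
#' @param Y mass fraction of the component within the fluid phase.
#' @param rho1 fluid density, kg/m^3.
#' @param M molar mass, kg/kmol (> 0).
#' @return Concentration in kmol/m^3.
#' @export
#' @examples
#' molar_concentration(1, 3.646e-4, 1000, 36.46)  # 0.01 kmol/m^3
molar_concentration <- function(alpha1, Y, rho1, M) {
  if (any(M <= 0)) stop("molar mass must be positive")
  alpha1 * Y * rho1 / M
}

#' pH from the hydrochloric-acid concentration
#'
#' pH = -log10(max(C0, c_floor)). The floor (default 1e-8 kmol/m^3) caps the
#' reported pH of acid-free fluid at 8, consistent with the alkaline
#' (pH 7.3-8.3) intestinal environment; buffering beyond acid consumption is
#' not modelled, so bicarbonate raises pH only by neutralizing acid.
#'
#' @param C0 acid concentration, kmol/m^3 (>= 0).
#' @param c_floor concentration floor, kmol/m^3.
#' @return pH value(s).
#' @export
#' @examples
#' ph_from_acid(0.01)  # pH 2
ph_from_acid <- function(C0, c_floor = 1e-8) {
  if (any(C0 < 0)) stop("acid concentration must be nonnegative")
  -log10(pmax(C0, c_floor))
}

#' Acid-bicarbonate neutralization rates
#'
#' Bimolecular neutralization NaHCO3 + HCl -> (NaCl + CO2) + H2O. The molar
#' rate is k02 * C0 * C2; component mass rates are the molar rate times the
#' molar masses, negative for the reagents (acid i = 0, bicarbonate i = 2) and
#' positive for the products (i = 1, water i = 9). With M0 + M2 = M1 + M9 the
#' four rates sum to zero exactly.
#'
#' @param C0,C2 acid and bicarbonate concentrations, kmol/m^3.
#' @param k02 rate constant, m^3/(kmol s).
#' @param registry a [component_registry()].
#' @return Named numeric vector of mass rates kg/(m^3 s) for components
#'   `HCl`, `reaction_product`, `NaHCO3`, `water`.
#' @export
neutralization_rates <- function(C0, C2, k02 = 1e4,
                                 registry = component_registry()) {
  if (any(C0 < 0) || any(C2 < 0)) stop("concentrations must be nonnegative")
  molar <- k02 * C0 * C2
  M <- registry$molar_mass
  c(HCl = -molar * M[1], reaction_product = molar * M[2],
    NaHCO3 = -molar * M[3], water = molar * M[10])
}

#' Pepsin pH activity modifier
#'
#' Quadratic activity profile f(pH) = max(0, a*pH^2 + b*pH + c). With the
#' default coefficients the optimum sits at pH 2.32 and activity vanishes
#' above pH 4.45 (and below pH 0.19).
#'
#' @param ph pH value(s).
#' @param a37,b37,c37 quadratic coefficients (a37 < 0).
#' @return Nonnegative modifier value(s).
#' @export
#' @examples
#' pepsin_ph_modifier(2.32)
#' pepsin_ph_modifier(5)  # 0
pepsin_ph_modifier <- function(ph, a37 = -5.786, b37 = 26.819, c37 = -4.857) {
  pmax(0, a37 * ph^2 + b37 * ph + c37)
}

#' Proteolysis rates (pepsin + protein -> polypeptides)
#'
#' Michaelis-Menten kinetics modified by the pepsin pH profile. In molar
#' terms the rate is k37 * f(pH) * C3 * C7 / (k37' + C3) kmol/(m^3 s); the
#' protein mass loss is M3 times that molar rate, which equals the product
#' form k37 * f * (alpha1 rho1)^2 Y3 Y7 / M7 / (k37' + alpha1 rho1 Y3 / M3).
#' Polypeptides gain exactly the protein mass loss (the registry assigns both
#' the same molar mass), so the pair conserves mass.
#'
#' @param alpha1 fluid volume fraction.
#' @param Y3,Y7 protein and pepsin mass fractions.
#' @param ph local pH.
#' @param rho1 fluid density, kg/m^3.
#' @param reaction the `reaction` block of a [gi_config()].
#' @param registry a [component_registry()].
#' @return List with `R3` (protein, <= 0) and `R8` (polypeptide, >= 0),
#'   kg/(m^3 s).
#' @export
proteolysis_rates <- function(alpha1, Y3, Y7, ph, rho1 = 1000,
                              reaction = gi_config()$reaction,
                              registry = component_registry()) {
  M3 <- registry$molar_mass[registry$name == "protein"]
  M7 <- registry$molar_mass[registry$name == "pepsin"]
  f <- pepsin_ph_modifier(ph, reaction$a37, reaction$b37, reaction$c37)
  num <- reaction$k37 * f * (alpha1 * rho1)^2 * Y3 * Y7 / M7
  den <- reaction$k37_prime + alpha1 * rho1 * Y3 / M3
  r <- ifelse(den > 0, num / den, 0)
  list(R3 = -r, R8 = r)
}

#' Exact bimolecular extent of neutralization over a time step
#'
#' Analytic solution of dC0/dt = dC2/dt = -k C0 C2, used so the stiff
#' neutralization (k02 = 1e4 m^3/(kmol s)) does not limit the transport time
#' step. Returns the reacted extent xi (kmol/m^3) with
#' C0(t) = C0 - xi, C2(t) = C2 - xi.
#'
#' @param C0,C2 initial concentrations, kmol/m^3 (vectors allowed).
#' @param k rate constant, m^3/(kmol s).
#' @param dt time interval, s.
#' @return Extent xi, kmol/m^3, with 0 <= xi <= min(C0, C2).
#' @export
neutralization_extent <- function(C0, C2, k, dt) {
  d <- C0 - C2
  xi <- numeric(length(C0))
  eq <- abs(d) < 1e-14 * pmax(C0, C2)
  # equal-concentration limit: xi = k C^2 t / (1 + k C t)
  xi[eq] <- k * C0[eq]^2 * dt / (1 + k * C0[eq] * dt)
  ne <- !eq & C0 > 0 & C2 > 0
  if (any(ne)) {
    lo <- pmin(C0[ne], C2[ne])
    hi <- pmax(C0[ne], C2[ne])
    e <- exp(-k * (hi - lo) * dt)    # in (0, 1]; underflow -> full depletion
    xi[ne] <- hi * lo * (1 - e) / (hi - lo * e)
  }
  pmin(pmax(xi, 0), pmin(C0, C2))
}
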