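#' Acid-dependent dissolution coefficient
#'
#' Mass-transfer coefficient from a food particle into the solution,
#' k = k_phys * a * pH^b (kg per m^2 of particle surface per second). The
#' power law is fitted so k = k_phys near the physiologically normal gastric
#' pH (~1.8); in a neutral or alkaline environment (pH >= `ph_cut`) the mass
#' exchange is zero.
#'
#' @param ph local pH (> 0).
#' @param k_phys reference mass-transfer coefficient, kg/(m^2 s).
#' @param a,b power-law parameters.
#' @param ph_cut pH at and above which dissolution stops.
#' @return k, kg/(m^2 s).
#' @export
#' @examples
#' dissolution_coefficient(2)  # ~2.07e-4
dissolution_coefficient <- function(ph, k_phys = 2.72e-4, a = 3.246,
                                    b = -2.092, ph_cut = 7) {
  if (any(ph <= 0)) stop("pH must be positive")
  ifelse(ph >= ph_cut, 0, k_phys * a * ph^b)
}

#' Particle-to-solution dissolution flux
#'
#' For spherical particles the specific surface is 6/d, so the volumetric
#' mass flux from bin j into dissolved component i is
#' m'(j)(i) = beta_i * 6 * k * alpha_j / d_j. The smallest bin
#' (nondigestible fibres) never dissolves.
#'
#' @param alpha_j bin volume fraction (>= 0).
#' @param d_j bin diameter, m (> 0).
#' @param k dissolution coefficient, kg/(m^2 s).
#' @param beta_i particle composition fraction(s) of the target component(s).
#' @param dissolvable FALSE for the terminal bin.
#' @return Flux(es) kg/(m^3 s), same shape as `beta_i`.
#' @export
particle_to_solution_flux <- function(alpha_j, d_j, k, beta_i,
                                      dissolvable = TRUE) {
  if (any(d_j <= 0)) stop("diameter must be positive")
  if (any(alpha_j < 0)) stop("volume fraction must be nonnegative")
  if (!dissolvable) return(beta_i * 0)
  beta_i * 6 * k * alpha_j / d_j
}

#' Size-bin cascade flux
#'
#' Mass transition from bin j to the next smaller bin j+1 as particles shrink
#' past the bin boundary: m''(j)(j+1) = 6 d_{j+1}^3 k alpha_j /
#' (d_j (d_j^3 - d_{j+1}^3)). The flux out of the terminal bin is zero by
#' convention, as is any flux into the largest bin.
#'
#' @param alpha_j donor-bin volume fraction.
#' @param d_j donor diameter, m.
#' @param d_next receiver diameter, m (0 < d_next < d_j); NA for the terminal
#'   bin, giving zero flux.
#' @param k dissolution coefficient, kg/(m^2 s).
#' @return Flux kg/(m^3 s).
#' @export
bin_cascade_flux <- function(alpha_j, d_j, d_next, k) {
  if (any(alpha_j < 0)) stop("volume fraction must be nonnegative")
  out <- rep(0, length(alpha_j))
  ok <- !is.na(d_next)
  if (any(ok)) {
    if (any(d_next[ok] <= 0) || any(d_j[ok] <= d_next[ok])) {
      stop("need d_j > d_next > 0")
    }
    out[ok] <- 6 * d_next[ok]^3 * k[ok] * alpha_j[ok] /
      (d_j[ok] * (d_j[ok]^3 - d_next[ok]^3))
  }
  out
}

#' Interphase drag coefficient
#'
#' Reynolds-corrected Stokes drag between a particle bin and the carrier
#' fluid, K(j)(1) = 18 alpha_j alpha_1 eta_1 / d_j^2 * (1 + 0.15 Re^0.687)
#' with Re = rho_1 |v_j - v_1| d_j / eta_1; and between two particle bins,
#' K(j)(q) = 72 alpha_j alpha_q eta_j / (d_j + d_q)^2 * (1 + 0.15 Re^0.687)
#' with Re = 0.5 rho_j |v_j - v_q| (d_j + d_q) / eta_j. The closure is
#' intended for Re <= 1000; above that a warning is issued and the same form
#' is applied. K is symmetric in its phase indices.
#'
#' @param alpha_j,alpha_q volume fractions.
#' @param d_j,d_q diameters, m (`d_q = NA` selects the fluid-particle form).
#' @param eta viscosity of the reference phase (fluid eta_1 for
#'   fluid-particle drag, particle eta_j for particle-particle), Pa s.
#' @param rho density of the reference phase, kg/m^3.
#' @param slip |v_j - v_q|, m/s.
#' @param warn_re warn when Re exceeds 1000.
#' @return K, kg/(m^3 s).
#' @export
#' @examples
#' drag_coefficient(0.1, 0.9, 1e-3, NA, eta = 1e-3, rho = 1000, slip = 0)
drag_coefficient <- function(alpha_j, alpha_q, d_j, d_q = NA, eta, rho,
                             slip = 0, warn_re = TRUE) {
  fluid <- is.na(d_q)
  re <- ifelse(fluid, rho * abs(slip) * d_j / eta,
               0.5 * rho * abs(slip) * (d_j + d_q) / eta)
  if (warn_re && any(re > 1000)) {
    warning("interphase Reynolds number exceeds 1000; drag closure applied ",
            "outside its stated range")
  }
  corr <- 1 + 0.15 * re^0.687
  ifelse(fluid,
         18 * alpha_j * alpha_q * eta / d_j^2 * corr,
         72 * alpha_j * alpha_q * eta / (d_j + d_q)^2 * corr)
}

#' Terminal slip velocity of a particle bin
#'
#' Drift-flux reduction of the momentum balance: the axial slip of bin j
#' relative to the fluid solves the terminal balance
#' K(j)(1) (v_1 - v_j) + alpha_j (rho_j - rho_mix) g_axis = 0, where K
#' depends on the slip through the Reynolds correction. Because K is
#' proportional to alpha_j alpha_1, the fixed point is
#' slip = (rho_j - rho_mix) g_axis d_j^2 /
#'        (18 alpha_1 eta_1 (1 + 0.15 Re(slip)^0.687)),
#' solved by a damped fixed-point iteration (tolerance and iteration cap from
#' `numerics`). The slip magnitude is capped at `numerics$slip_cap` and the
#' fluid fraction floored at 0.05 for robustness in particle-packed cells.
#'
#' @param alpha1 fluid volume fraction.
#' @param d_j bin diameter, m.
#' @param rho_j bin density, kg/m^3.
#' @param rho_mix local mixture density Sum alpha_j rho_j, kg/m^3.
#' @param g_axis signed axial gravity component, m/s^2.
#' @param eta1,rho1 fluid viscosity and density.
#' @param numerics the `numerics` block of a [gi_config()].
#' @param s0 optional warm start for the iteration (e.g. the slip from the
#'   previous time step); defaults to the uncorrected Stokes value.
#' @return Signed slip v_j - v_1, m/s (vectorized over inputs).
#' @export
slip_velocity <- function(alpha1, d_j, rho_j, rho_mix, g_axis,
                          eta1 = 1e-3, rho1 = 1000,
                          numerics = gi_config()$numerics, s0 = NULL) {
  a1 <- pmax(alpha1, 0.05)
  drive <- (rho_j - rho_mix) * g_axis * d_j^2 / (18 * a1 * eta1)
  s <- if (is.null(s0)) drive else s0   # Stokes or warm start
  cre <- 0.15 * (rho1 * d_j / eta1)^0.687
  for (it in seq_len(numerics$slip_maxit)) {
    s_new <- 0.5 * s + 0.5 * drive / (1 + cre * abs(s)^0.687)
    if (max(abs(s_new - s)) < numerics$slip_tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  pmax(pmin(s, numerics$slip_cap), -numerics$slip_cap)
}
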