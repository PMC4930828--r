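#' Build the initial simulation state
#'
#' The food bolus (chewed carrot, 20 chewing cycles) occupies the antral
#' bulge: cells with x <= `fill_end` receive the standard initial volume
#' fractions (fluid 0.4; bins 3.6/2.8/1.7/0.7/0.2 mm at
#' 0.044/0.110/0.344/0.088/0.014); all other cells are pure fluid. The fluid
#' phase starts as pure water (Y_water = 1, density 1000 kg/m^3): acid,
#' bicarbonate, pepsin and dissolved food all build up from secretion and
#' dissolution during the run. Velocities start at zero.
#'
#' @param geom a [gi_geometry()].
#' @param config a [gi_config()].
#' @param scenario a [load_scenario()] result (or id) fixing the particle
#'   density.
#' @param fill optional list overriding the fill: `alpha` (length 6), `Y`
#'   (length 10), `cells` (logical or index vector). An empty `cells`
#'   selection yields an all-water domain.
#' @return List with matrices `Cm` (n x 10 component masses, kg) and `P`
#'   (n x 6 phase masses, kg), plus `Vcell` (m^3).
#' @export
make_initial_state <- function(geom, config = gi_config(), scenario = 1,
                               fill = NULL) {
  if (is.numeric(scenario)) scenario <- load_scenario(scenario)
  alpha_fill <- c(0.4, 0.044, 0.110, 0.344, 0.088, 0.014)
  Y0 <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1)
  cells <- geom$fill
  if (!is.null(fill)) {
    if (!is.null(fill$alpha)) alpha_fill <- fill$alpha
    if (!is.null(fill$Y)) Y0 <- fill$Y
    if (!is.null(fill$cells)) cells <- fill$cells
  }
  stopifnot(abs(sum(alpha_fill) - 1) < 1e-9, abs(sum(Y0) - 1) < 1e-9)
  if (any(which(cells) > sum(geom$antral))) {
    stop("fill region must lie inside the stomach")
  }
  rho <- c(config$fluid$rho, rep(scenario$particle_density, 5))
  R0 <- wall_radius(geom$x, 0, config)
  Vcell <- pi * R0^2 * geom$dx
  alpha <- matrix(rep(c(1, 0, 0, 0, 0, 0), each = geom$n), geom$n, 6)
  alpha[cells, ] <- matrix(rep(alpha_fill, each = sum(cells)), ncol = 6)
  P <- sweep(alpha, 2, rho, "*") * Vcell
  Cm <- outer(P[, 1], Y0)
  list(Cm = Cm, P = P, Vcell = Vcell)
}
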