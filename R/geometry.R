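#' Baseline radius profile of the antroduodenal tract
#'
#' Quasi-1D reduction: cross-sections are circles of equivalent area. The
#' default profile is piecewise smooth: an antral bulge (maximum radius at the
#' closed proximal end) tapering as cos^2 toward the pyloric constriction, a
#' short narrow pylorus, and a uniform duodenal tube.
#'
#' @param x arclength coordinate(s) along the centerline, m.
#' @param config a [gi_config()].
#' @return Baseline radius R0(x), m.
#' @export
r0_profile <- function(x, config = gi_config()) {
  g <- config$geometry
  la <- g$antrum_length
  lp <- g$pylorus_length
  L <- la + lp + g$duodenum_length
  r <- numeric(length(x))
  ant <- x <= la
  r[ant] <- g$antrum_r_end +
    (g$antrum_r_max - g$antrum_r_end) * cos(pi / 2 * x[ant] / la)^2
  pyl <- x > la & x <= la + lp
  r[pyl] <- g$pylorus_radius
  duo <- x > la + lp
  r[duo] <- g$duodenum_radius
  r[x < 0 | x > L] <- NA_real_
  r
}

region_of <- function(x, config) {
  g <- config$geometry
  la <- g$antrum_length
  lp <- g$pylorus_length
  reg <- integer(length(x))
  reg[x <= g$region2_end] <- 2L
  reg[x > g$region2_end & x <= la] <- 3L
  reg[x > la & x <= la + lp] <- 0L  # pylorus: no secretion
  duo <- x - (la + lp)
  reg[duo > 0 & duo <= g$region4_end] <- 4L
  reg[duo > g$region4_end & duo <= g$region5_end] <- 5L
  reg
}

#' Build the discretized tract geometry
#'
#' Produces the finite-volume grid: cell centers, baseline radii, wall-region
#' labels (2: acid-secreting antrum, 3: bicarbonate antrum, 4: duodenum,
#' 5: pancreatic inflow, 0: pylorus/terminal tube), per-cell gravity cosine
#' (projection of gravity on the centerline for the default upright posture),
#' and the pyloric gate interface.
#'
#' @param config a [gi_config()].
#' @return A list of class `gi_geometry`: `n`, `dx`, `x` (cell centers), `xf`
#'   (faces), `R0`, `region`, `gravity` (signed axial gravity cosine),
#'   `is_pylorus`, `gate_face` (face index of the gate), `antral` (logical,
#'   cells upstream of the gate), `fill` (logical, initially food-filled
#'   cells), `L`, `gate_phase` (s).
#' @export
gi_geometry <- function(config = gi_config()) {
  g <- config$geometry
  dx <- config$numerics$dx
  L <- g$antrum_length + g$pylorus_length + g$duodenum_length
  n <- round(L / dx)
  xf <- seq(0, L, length.out = n + 1)
  x <- (xf[-1] + xf[-(n + 1)]) / 2
  R0 <- r0_profile(x, config)
  region <- region_of(x, config)
  la <- g$antrum_length
  lp <- g$pylorus_length
  gravity <- ifelse(x <= la, g$gravity_antrum,
                    ifelse(x <= la + lp, 0, g$gravity_duodenum))
  gate_x <- la + lp / 2
  gate_face <- which.min(abs(xf - gate_x))
  w <- config$waves$antral
  phase <- config$gate$phase
  if (is.null(phase)) {
    # gate opens when the antral wave front reaches mid-antrum
    phase <- ((la / 2 - w$origin) / w$speed) %% config$gate$period
  }
  structure(list(
    n = n, dx = dx, x = x, xf = xf, R0 = R0, region = region,
    gravity = gravity, is_pylorus = x > la & x <= la + lp,
    gate_face = gate_face, antral = x < gate_x,
    fill = x <= g$fill_end, L = L, gate_phase = phase
  ), class = "gi_geometry")
}

#' Tract wall radius under peristaltic forcing
#'
#' Superimposes the travelling antral and duodenal contraction waves on the
#' baseline profile. Each wave is a sin^2-shaped indentation of nominal
#' amplitude A scaled by the motor functionality F(l)(3) of the local wall
#' region, travelling at the wave speed for the wave duration; the amplitude
#' is ramped linearly over the first and last seconds of the wave's life
#' (`config$waves$ramp`) so wall volume changes are continuous. Antral waves
#' start every 18 s at the proximal end; duodenal waves start every 9 s at the
#' pylorus exit. The radius never drops below `config$geometry$r_floor`. The
#' pylorus wall is rigid; optionally (`gate = TRUE`) its radius reports the
#' gate state (0 when closed).
#'
#' @param x position(s), m.
#' @param t time, s (scalar).
#' @param config a [gi_config()].
#' @param motor motor functionality: a single number or a [functionality_map()]
#'   (its "motor" column is used, by wall region at `x`).
#' @param gate if TRUE, report the gated radius inside the pylorus.
#' @return Radius R(x, t), m.
#' @export
#' @examples
#' cfg <- gi_config()
#' wall_radius(0.05, 0)           # baseline, no wave at t = 0 yet at x = 0.05
#' wall_radius(0.05, 25, cfg)     # first antral wave near mid-antrum
wall_radius <- function(x, t, config = gi_config(), motor = 1, gate = FALSE) {
  stopifnot(length(t) == 1L, t >= 0)
  g <- config$geometry
  la <- g$antrum_length
  lp <- g$pylorus_length
  r <- r0_profile(x, config)
  if (is.matrix(motor)) {
    reg <- region_of(x, config)
    Fm <- rep(1, length(x))
    sel <- reg >= 2
    Fm[sel] <- motor[as.character(reg[sel]), "motor"]
  } else {
    Fm <- rep(motor, length.out = length(x))
  }
  depth <- numeric(length(x))
  add_waves <- function(wp, x0, xmax, depth) {
    ms <- seq(floor((t - wp$duration) / wp$period), floor(t / wp$period))
    ms <- ms[ms >= 0]
    for (m in ms) {
      tau <- t - m * wp$period
      if (tau < 0 || tau > wp$duration) next
      env <- min(1, tau / config$waves$ramp, (wp$duration - tau) / config$waves$ramp)
      if (env <= 0) next
      xc <- x0 + wp$speed * tau
      xi <- x - xc
      inside <- abs(xi) <= wp$width / 2 & x <= xmax
      depth[inside] <- depth[inside] +
        wp$amplitude * env * cos(pi * xi[inside] / wp$width)^2
    }
    depth
  }
  wa <- config$waves$antral
  depth <- add_waves(wa, wa$origin, la, depth)
  wd <- config$waves$duodenal
  depth <- add_waves(wd, la + lp, g$antrum_length + lp + g$duodenum_length, depth)
  pyl <- x > la & x <= la + lp
  rr <- pmax(r - depth * Fm, g$r_floor)
  rr[pyl] <- g$pylorus_radius  # rigid pylorus wall; gating is a flux switch
  if (gate && !gate_open(t, config)) rr[pyl] <- 0
  rr
}

#' Pyloric gate state
#'
#' The gastric outlet opens for `open_duration` seconds once per `period`
#' (defaults 2 s every 18 s). The phase is chosen so that an opening coincides
#' with the arrival of the antral contraction wave at mid-antrum, synchronizing
#' antral, pyloric and duodenal motor activity; it can be overridden via
#' `config$gate$phase`.
#'
#' @param t time(s), s.
#' @param config a [gi_config()].
#' @param phase optional gate phase (s); defaults to the synchronized value.
#' @return Logical: TRUE when the gate is open.
#' @export
gate_open <- function(t, config = gi_config(), phase = NULL) {
  if (is.null(phase)) {
    w <- config$waves$antral
    phase <- ((config$geometry$antrum_length / 2 - w$origin) / w$speed) %%
      config$gate$period
  }
  ((t - phase) %% config$gate$period) < config$gate$open_duration
}

#' Cell volumes of the moving-wall grid
#'
#' Finite-volume cell volumes V = pi R(x, t)^2 dx for circular cross-sections,
#' with time derivatives from a centered difference.
#'
#' @param t time, s.
#' @param geom a [gi_geometry()].
#' @param config a [gi_config()].
#' @param motor motor functionality, as in [wall_radius()].
#' @param dt_deriv half-width of the derivative stencil, s.
#' @return List with `V` (m^3) and `dVdt` (m^3/s), one entry per cell.
#' @export
cell_volumes <- function(t, geom, config = gi_config(), motor = 1,
                         dt_deriv = 1e-3) {
  R <- wall_radius(geom$x, t, config, motor)
  V <- pi * R^2 * geom$dx
  tm <- max(t - dt_deriv, 0)
  Rp <- wall_radius(geom$x, t + dt_deriv, config, motor)
  Rm <- wall_radius(geom$x, tm, config, motor)
  dVdt <- pi * (Rp^2 - Rm^2) * geom$dx / (t + dt_deriv - tm)
  list(V = V, dVdt = dVdt)
}

#' Write / read the geometry table
#'
#' Plain-text table (x, R0, region, gravity cosine) with a header line, as a
#' portable description of the discretized tract.
#'
#' @param geom a `gi_geometry`.
#' @param path file path.
#' @return `read_geometry` returns a `gi_geometry` (gate/fill metadata are
#'   reconstructed from `config`); `write_geometry` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  df <- data.frame(x = geom$x, R0 = geom$R0, region = geom$region,
                   gravity = geom$gravity)
  utils::write.table(format(df, digits = 12), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @param config a [gi_config()] supplying the non-tabulated metadata.
#' @export
read_geometry <- function(path, config = gi_config()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  geom <- gi_geometry(config)
  stopifnot(nrow(df) == geom$n)
  geom$x <- df$x
  geom$R0 <- df$R0
  geom$region <- as.integer(df$region)
  geom$gravity <- df$gravity
  geom
}
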