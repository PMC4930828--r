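#' One-dimensional incompressibility: interface volume fluxes
#'
#' Integrates the quasi-1D continuity relation
#' dV_i/dt + Phi_{i+1/2} - Phi_{i-1/2} = Q_i
#' from the closed esophageal end, giving the total volume flux Phi through
#' every cell face. `dVdt` is the prescribed wall-motion volume rate per cell
#' and `Q` the volumetric source (secreted fluid). When the pyloric gate is
#' closed, the flux at the gate face is zero and the antral segment is made
#' self-consistent by a compliance correction: the net wall-volume imbalance
#' of the sealed antrum is redistributed over its cells in proportion to
#' their volume (receptive relaxation of the stomach wall), so no flux
#' crosses the closed proximal boundary either. The duodenal segment then
#' re-anchors at the gate and vents through the open distal boundary.
#'
#' @param dVdt prescribed wall volume rates per cell, m^3/s.
#' @param Q volumetric sources per cell, m^3/s.
#' @param Vcell current cell volumes, m^3 (compliance weights).
#' @param geom a [gi_geometry()].
#' @param gate_is_open logical.
#' @return List with `Phi` (length n+1, m^3/s; `Phi[1] = 0`) and the
#'   effective `dVdt` after any compliance correction.
#' @export
mixture_velocity <- function(dVdt, Q, Vcell, geom, gate_is_open) {
  n <- geom$n
  gf <- geom$gate_face
  if (!gate_is_open) {
    ac <- seq_len(gf - 1L)
    B <- sum(dVdt[ac] - Q[ac])
    dVdt[ac] <- dVdt[ac] - B * Vcell[ac] / sum(Vcell[ac])
  }
  net <- Q - dVdt
  Phi <- c(0, cumsum(net))
  if (!gate_is_open) {
    Phi[gf] <- 0
    Phi[(gf + 1L):(n + 1L)] <- cumsum(net[gf:n])
  }
  list(Phi = Phi, dVdt = dVdt)
}

# Upwind face flux of one density column, optionally with MUSCL/minmod
# reconstruction (TVD second order in smooth regions).
# c: n cell densities (kg/m^3); v: n+1 face velocities; Af: n+1 face areas.
# Closed left end; zero-gradient right end.
flux_upwind <- function(c, v, Af, order2 = TRUE) {
  n <- length(c)
  f <- numeric(n + 1)
  if (order2 && n >= 3) {
    d <- diff(c)
    a <- d[1:(n - 2)]
    b <- d[2:(n - 1)]
    sl <- numeric(n)                       # limited slope times dx
    sl[2:(n - 1)] <- 0.5 * (sign(a) + sign(b)) * pmin(abs(a), abs(b))
    cl <- c[1:(n - 1)] + 0.5 * sl[1:(n - 1)]
    cr <- c[2:n] - 0.5 * sl[2:n]
  } else {
    cl <- c[1:(n - 1)]
    cr <- c[2:n]
  }
  vi <- v[2:n]
  f[2:n] <- Af[2:n] * (pmax(vi, 0) * cl + pmin(vi, 0) * cr)
  f[n + 1] <- Af[n + 1] * v[n + 1] * c[n]
  f
}

# One adaptive substep of the 1D solver. sim is the internal state list.
# Returns the updated sim; the step actually taken is sim$dt_last.
gi_substep <- function(sim, dt_want) {
  g <- sim$geom
  pars <- sim$pars
  num <- sim$config$numerics
  n <- g$n
  rho <- pars$rho

  # phases 2..6 share one density, so the per-column division is scalar
  Vph <- sim$P / rho[2]
  Vph[, 1] <- sim$P[, 1] / rho[1]
  Vcell <- rowSums(Vph)
  alpha <- Vph / Vcell

  Rnow <- sim$Rnow
  A_now <- pi * Rnow^2
  Vw_now <- A_now * g$dx

  ## volumetric secretion sources
  conc <- gi_region_conc(sim$Cm, Vcell, sim$reg_idx)
  rates <- gi_secretion_rates(conc, pars)
  Q <- numeric(n)
  for (l in names(rates)) {
    ix <- sim$reg_idx[[l]]
    Q[ix] <- Q[ix] + sum(rates[[l]]) / rho[1] * Vcell[ix] / sum(Vcell[ix])
  }

  gate_now <- gate_open(sim$t, sim$config, g$gate_phase)

  ## drift-flux slip (cell-centered, along the axis)
  rho_mix <- drop(alpha %*% rho)
  g_axis <- g$gravity * sim$config$geometry$g
  S <- matrix(0, n, 5)
  for (j in 2:6) {
    S[, j - 1] <- slip_velocity(alpha[, 1], pars$d[j], rho[j], rho_mix,
                                g_axis, pars$eta1, rho[1], num,
                                s0 = sim$S_prev[, j - 1])
  }
  sim$S_prev <- S
  v1corr <- -rowSums(alpha[, 2:6, drop = FALSE] * S)

  face_mid <- function(z) c(z[1], (z[1:(n - 1)] + z[2:n]) / 2, z[n])
  Aint <- pmin(A_now[1:(n - 1)], A_now[2:n])
  Af <- c(A_now[1], Aint, A_now[n])
  v1cf <- face_mid(v1corr)
  Sf <- rbind(S[1, ], (S[1:(n - 1), ] + S[2:n, ]) / 2, S[n, ])

  dt <- dt_want
  for (try in 1:8) {
    R_new <- wall_radius(g$x, sim$t + dt, sim$config, motor = sim$scenario$F)
    Vw_new <- pi * R_new^2 * g$dx
    dVdt <- (Vw_new - Vw_now) / dt + (Vw_now - Vcell) / num$tau_relax
    mv <- mixture_velocity(dVdt, Q, Vcell, g, gate_now)
    uf <- mv$Phi / Af
    v1f <- uf + v1cf
    Vjf <- Sf + v1f
    v1f[1] <- 0
    Vjf[1, ] <- 0
    if (!gate_now) {
      v1f[g$gate_face] <- 0
      Vjf[g$gate_face, ] <- 0
    }
    vmax <- max(abs(v1f), abs(Vjf))
    dt_cfl <- num$cfl * g$dx / max(vmax, 1e-12)
    if (dt <= dt_cfl) break
    dt <- dt_cfl * 0.95
    if (dt < 1e-7) stop("time step collapsed below 1e-7 s at t = ", sim$t)
  }

  ## advection
  ord2 <- num$advection_order >= 2
  Cm <- sim$Cm
  P <- sim$P
  for (j in 2:6) {
    f <- flux_upwind(P[, j] / Vcell, Vjf[, j - 1], Af, ord2)
    P[, j] <- P[, j] - dt * diff(f)
    sim$evac_phase[j] <- sim$evac_phase[j] + f[n + 1] * dt
  }
  rho1K <- rho[1] * pars$K_diff
  if (num$diffusion) {
    Y <- Cm / pmax(P[, 1], 1e-300)
    a1f_int <- (alpha[1:(n - 1), 1] + alpha[2:n, 1]) / 2
  }
  for (i in 1:10) {
    f <- flux_upwind(Cm[, i] / Vcell, v1f, Af, ord2)
    if (num$diffusion) {
      f[2:n] <- f[2:n] -
        Aint * a1f_int * rho1K[i] * (Y[2:n, i] - Y[1:(n - 1), i]) / g$dx
    }
    Cm[, i] <- Cm[, i] - dt * diff(f)
    sim$evac_comp[i] <- sim$evac_comp[i] + f[n + 1] * dt
    sim$evac_phase[1] <- sim$evac_phase[1] + f[n + 1] * dt
  }

  ## clip stray negatives (roundoff-level; ledgered)
  neg <- Cm < 0
  if (any(neg)) {
    sim$clip_added <- sim$clip_added - sum(Cm[neg])
    Cm[neg] <- 0
  }
  negp <- P[, 2:6] < 0
  if (any(negp)) {
    sim$clip_added <- sim$clip_added - sum(P[, 2:6][negp])
    P[, 2:6][negp] <- 0
  }
  P[, 1] <- rowSums(Cm)

  ## local sources
  Vcell_new <- P[, 1] / rho[1] + rowSums(P[, 2:6, drop = FALSE] / rho[2])
  up <- gi_local_sources(Cm, P, Vcell_new, dt, sim$reg_idx, pars)
  sim$Cm <- up$Cm
  sim$P <- up$P
  sim$secreted <- sim$secreted + up$secreted
  sim$absorbed <- sim$absorbed + up$absorbed

  sim$t <- sim$t + dt
  sim$Rnow <- R_new
  sim$dt_last <- dt
  sim
}

#' Run a digestion scenario on the quasi-1D solver
#'
#' Integrates the coupled multiphase system from the standard initial state:
#' peristaltic wall motion and pyloric gating force the mixture flow
#' (1D incompressibility), particle bins are advected with their drift-flux
#' slip and the fluid with a compensating counterflow, dissolved components
#' are advected and diffuse, and all local sources (secretion, absorption,
#' dissolution, cascade, neutralization, proteolysis) act per cell. Operator
#' splitting per substep: wall motion and mixture velocity; upwind advection
#' of phases and components; diffusion; local sources. The substep length
#' adapts to the CFL condition.
#'
#' @param scenario scenario id 1..6 or a [load_scenario()] list.
#' @param T simulated horizon, s (presets: 306 for the disorder comparison,
#'   900 for the 15-minute evacuation stage).
#' @param config a [gi_config()].
#' @param output_dt time-series recording interval, s.
#' @param fill optional initial-fill override, see [make_initial_state()].
#' @param geom optional pre-built [gi_geometry()] (e.g. with edited region
#'   labels); defaults to `gi_geometry(config)`.
#' @param init optional initial state override: a list with matrices `Cm`
#'   (n x 10) and `P` (n x 6) of component/phase masses in kg, bypassing
#'   [make_initial_state()] for custom experiments.
#' @param progress print progress every 60 model-seconds.
#' @return An object of class `gi_sim`: `series` (data.frame time series),
#'   `ph_profiles` (per-cell pH snapshots), `final` state, cumulative
#'   `ledgers`, the `geom`, `config`, `scenario` used, `closure` (global
#'   mass-balance error, relative) and `valid` (FALSE if the cumulative
#'   clipped mass exceeded `numerics$clip_tol` of the initial mass).
#' @export
#' @examples
#' \donttest{
#' sim <- gi_run(1, T = 36)
#' print(sim)
#' }
gi_run <- function(scenario = 1, T = 306, config = gi_config(),
                   output_dt = config$output$dt, fill = NULL,
                   geom = NULL, init = NULL, progress = FALSE) {
  stopifnot(T >= 0)
  if (is.numeric(scenario)) scenario <- load_scenario(scenario)
  if (is.null(geom)) geom <- gi_geometry(config)
  pars <- gi_pars(config, scenario)
  if (is.null(init)) init <- make_initial_state(geom, config, scenario, fill)
  reg_idx <- lapply(stats::setNames(2:5, as.character(2:5)),
                    function(l) which(geom$region == l))
  sim <- list(
    geom = geom, config = config, scenario = scenario, pars = pars,
    Cm = init$Cm, P = init$P, t = 0,
    Rnow = wall_radius(geom$x, 0, config, motor = scenario$F),
    reg_idx = reg_idx,
    evac_phase = numeric(6), evac_comp = numeric(10),
    secreted = numeric(10), absorbed = 0, clip_added = 0, dt_last = NA,
    S_prev = matrix(0, geom$n, 5)
  )
  mass0 <- sum(sim$P)
  init_phase_mass <- colSums(sim$P)

  comp_names <- component_registry()$name
  rec_times <- seq(0, T, by = output_dt)
  if (rec_times[length(rec_times)] < T) rec_times <- c(rec_times, T)
  ph_times <- seq(0, T, by = config$output$ph_every)
  rows <- vector("list", length(rec_times))
  ph_list <- list()

  record <- function(k) {
    Vph <- sweep(sim$P, 2, pars$rho, "/")
    Vcell <- rowSums(Vph)
    C0 <- sim$Cm[, 1] / (Vcell * pars$M[1])
    ph <- -log10(pmax(C0, pars$c_floor))
    sto <- geom$antral
    row <- c(
      time = sim$t,
      stats::setNames(colSums(sim$P[sto, , drop = FALSE]),
                      paste0("stomach_p", 1:6)),
      stats::setNames(colSums(sim$P[!sto, , drop = FALSE]),
                      paste0("duodenum_p", 1:6)),
      stats::setNames(colSums(sim$Cm), paste0("m_", comp_names)),
      stats::setNames(sim$evac_phase, paste0("evac_p", 1:6)),
      evac_chemical = sim$evac_comp[7],
      absorbed = sim$absorbed,
      secreted = sum(sim$secreted),
      ph_stomach_mean = sum(ph[sto] * Vcell[sto]) / sum(Vcell[sto]),
      ph_stomach_min = min(ph[sto]),
      ph_duodenum_mean = sum(ph[!sto] * Vcell[!sto]) / sum(Vcell[!sto]),
      ph_duodenum_min = min(ph[!sto]),
      closure = (sum(sim$P) + sum(sim$evac_phase) + sim$absorbed -
                   sum(sim$secreted) - sim$clip_added - mass0) / mass0
    )
    rows[[k]] <<- row
    if (any(abs(sim$t - ph_times) < output_dt / 2)) {
      ph_list[[length(ph_list) + 1]] <<- c(time = sim$t, ph)
    }
  }

  record(1)
  k <- 2
  steps <- 0
  dt_want <- config$numerics$dt_max
  while (k <= length(rec_times)) {
    target <- rec_times[k]
    while (sim$t < target - 1e-9) {
      sim <- gi_substep(sim, min(dt_want, target - sim$t))
      steps <- steps + 1
      if (steps > config$numerics$max_substeps) {
        stop("exceeded maximum number of substeps")
      }
    }
    record(k)
    if (progress && (target %% 60 < output_dt)) {
      message(sprintf("t = %.0f s (%d substeps)", sim$t, steps))
    }
    k <- k + 1
  }

  series <- as.data.frame(do.call(rbind, rows))
  ph_profiles <- do.call(rbind, ph_list)
  Vph <- sweep(sim$P, 2, pars$rho, "/")
  Vcell <- rowSums(Vph)
  final <- list(
    Cm = sim$Cm, P = sim$P, Vcell = Vcell, alpha = Vph / Vcell,
    Y = sim$Cm / pmax(sim$P[, 1], 1e-300),
    ph = -log10(pmax(sim$Cm[, 1] / (Vcell * pars$M[1]), pars$c_floor))
  )
  # net production of each phase by dissolution/cascade (in-domain + evacuated)
  total_change <- colSums(sim$P) + sim$evac_phase - init_phase_mass
  valid <- sim$clip_added <= config$numerics$clip_tol * mass0
  if (!valid) {
    warning("cumulative clipped mass ", format(sim$clip_added),
            " kg exceeds tolerance; run flagged invalid")
  }
  structure(list(
    series = series, ph_profiles = ph_profiles, final = final,
    ledgers = list(evac_phase = sim$evac_phase, evac_comp = sim$evac_comp,
                   secreted = sim$secreted, absorbed = sim$absorbed,
                   clip_added = sim$clip_added),
    init_phase_mass = init_phase_mass,
    phase_change_pct = 100 * total_change / init_phase_mass,
    closure = series$closure[nrow(series)],
    valid = valid,
    scenario = sim$scenario, config = config, geom = geom,
    T = T, substeps = steps
  ), class = "gi_sim")
}
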