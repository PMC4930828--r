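# Shared local (within-cell) physics: secretion, absorption, dissolution,
# size-bin cascade, neutralization and proteolysis, applied over a time step.
# The same code path serves the 0D batch reactor (one cell that carries all
# wall regions) and the quasi-1D solver (cells grouped into wall regions), so
# the two modes are algebraically identical for spatially uniform states.

# Precompute run constants into a flat list for speed.
gi_pars <- function(config, scenario) {
  reg <- component_registry()
  dens <- scenario$particle_density
  list(
    M = reg$molar_mass,
    K_diff = reg$diffusion,
    rho = c(config$fluid$rho, rep(dens, 5)),
    eta1 = config$fluid$eta,
    d = c(NA, config$particle$diameters),    # index by phase 1..6
    beta_cols = c(4L, 5L, 6L, 7L, 10L),      # protein, fat, carb, chem, water
    beta = unname(config$particle$beta),
    k02 = config$reaction$k02,
    reaction = config$reaction,
    diss = config$dissolution,
    c_floor = config$ph$c_floor,
    sec = config$secretion,
    abs = config$absorption,
    Fm = scenario$F
  )
}

# Regional secretion mass rates (kg/s) from regional mean concentrations.
# conc: list per region of named concentrations (kg/m^3). Returns a list per
# region of sparse component-rate vectors (length 10).
gi_secretion_rates <- function(conc, pars) {
  out <- list()
  Fm <- pars$Fm
  if (!is.null(conc[["2"]])) {
    cc <- conc[["2"]]
    F21 <- Fm["2", "secretion"]
    ac <- acid_secretion(cc[c("protein", "fat", "carbohydrate")],
                         pars$sec$acid, F21)
    pep <- pepsin_secretion(cc[["protein"]], pars$sec$pepsin, F21)
    v <- numeric(10)
    v[1] <- ac$acid; v[8] <- pep; v[10] <- ac$water
    out[["2"]] <- v
  }
  for (l in 3:5) {
    if (is.null(conc[[as.character(l)]])) next
    cc <- conc[[as.character(l)]]
    bc <- bicarbonate_secretion(cc[["HCl"]], l, pars$sec$bicarbonate,
                                Fm[as.character(l), "secretion"])
    v <- numeric(10)
    v[3] <- bc$bicarbonate; v[10] <- bc$water
    out[[as.character(l)]] <- v
  }
  out
}

# Regional mean concentrations (kg/m^3) of the components needed by the
# secretion laws. reg_idx: named list region -> cell indices.
gi_region_conc <- function(Cm, Vcell, reg_idx) {
  out <- list()
  for (l in names(reg_idx)) {
    ix <- reg_idx[[l]]
    if (!length(ix)) next
    vol <- sum(Vcell[ix])
    out[[l]] <- c(HCl = sum(Cm[ix, 1]) / vol,
                  protein = sum(Cm[ix, 4]) / vol,
                  fat = sum(Cm[ix, 5]) / vol,
                  carbohydrate = sum(Cm[ix, 6]) / vol)
  }
  out
}

# Apply all local sources over dt. Cm: n x 10 component masses (kg);
# P: n x 6 phase masses; Vcell: n cell volumes. Returns updated matrices and
# ledger increments.
gi_local_sources <- function(Cm, P, Vcell, dt, reg_idx, pars) {
  secreted <- numeric(10)
  absorbed <- 0

  ## --- secretion (adds fluid-phase mass with fixed gland composition)
  conc <- gi_region_conc(Cm, Vcell, reg_idx)
  rates <- gi_secretion_rates(conc, pars)
  for (l in names(rates)) {
    ix <- reg_idx[[l]]
    w <- Vcell[ix] / sum(Vcell[ix])
    dm <- outer(w, rates[[l]] * dt)   # kg per cell per component
    Cm[ix, ] <- Cm[ix, ] + dm
    secreted <- secreted + rates[[l]] * dt
  }

  ## --- absorption of the trace chemical through the wall layer
  for (l in names(reg_idx)) {
    ix <- reg_idx[[l]]
    if (!length(ix)) next
    Fl2 <- pars$Fm[l, "absorption"]
    c6 <- Cm[ix, 7] / Vcell[ix]
    src <- absorption_flux(c6, pars$abs, Fl2)   # kg/(m^3 s), <= 0
    dm <- src * pars$abs$layer_frac * Vcell[ix] * dt
    dm <- pmax(dm, -Cm[ix, 7])                  # cannot overdraw
    Cm[ix, 7] <- Cm[ix, 7] + dm
    absorbed <- absorbed - sum(dm)
  }

  ## --- dissolution and size-bin cascade (needs pH)
  C0 <- Cm[, 1] / (Vcell * pars$M[1])
  ph <- -log10(pmax(C0, pars$c_floor))
  kdis <- (ph < pars$diss$ph_cut) * pars$diss$k_phys * pars$diss$a *
    ph^pars$diss$b
  alpha_p <- (P[, 2:6, drop = FALSE] / pars$rho[2]) / Vcell
  for (j in 2:5) {                      # bin 6 neither dissolves nor cascades
    aj <- alpha_p[, j - 1]
    r_dis <- 6 * kdis * aj / pars$d[j]
    dn <- pars$d[j + 1]
    r_cas <- 6 * dn^3 * kdis * aj / (pars$d[j] * (pars$d[j]^3 - dn^3))
    dm_dis <- r_dis * Vcell * dt
    dm_cas <- r_cas * Vcell * dt
    tot <- dm_dis + dm_cas
    f <- pmin(1, P[, j] / pmax(tot, 1e-300))
    dm_dis <- dm_dis * f
    dm_cas <- dm_cas * f
    P[, j] <- P[, j] - dm_dis - dm_cas
    P[, j + 1] <- P[, j + 1] + dm_cas
    Cm[, pars$beta_cols] <- Cm[, pars$beta_cols] +
      outer(dm_dis, pars$beta)
  }

  ## --- neutralization (exact bimolecular step; stiff)
  C0 <- Cm[, 1] / (Vcell * pars$M[1])
  C2 <- Cm[, 3] / (Vcell * pars$M[3])
  xi <- neutralization_extent(C0, C2, pars$k02, dt)
  mol <- xi * Vcell                      # kmol reacted per cell
  Cm[, 1] <- pmax(Cm[, 1] - mol * pars$M[1], 0)
  Cm[, 3] <- pmax(Cm[, 3] - mol * pars$M[3], 0)
  Cm[, 2] <- Cm[, 2] + mol * pars$M[2]
  Cm[, 10] <- Cm[, 10] + mol * pars$M[10]

  ## --- proteolysis (protein -> polypeptide, mass conserving)
  C0 <- Cm[, 1] / (Vcell * pars$M[1])
  ph <- -log10(pmax(C0, pars$c_floor))
  f37 <- pepsin_ph_modifier(ph, pars$reaction$a37, pars$reaction$b37,
                            pars$reaction$c37)
  C3 <- Cm[, 4] / (Vcell * pars$M[4])
  C7 <- Cm[, 8] / (Vcell * pars$M[8])
  r_mol <- pars$reaction$k37 * f37 * C3 * C7 / (pars$reaction$k37_prime + C3)
  dm <- pmin(r_mol * pars$M[4] * Vcell * dt, Cm[, 4])
  Cm[, 4] <- Cm[, 4] - dm
  Cm[, 9] <- Cm[, 9] + dm

  P[, 1] <- rowSums(Cm)
  list(Cm = Cm, P = P, secreted = secreted, absorbed = absorbed)
}
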