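test_that("mixture velocity: no wall motion and no sources give no flow;
           a closed gate decouples the segments", {
  geom <- gi_geometry()
  n <- geom$n
  V <- pi * geom$R0^2 * geom$dx
  mv <- mixture_velocity(numeric(n), numeric(n), V, geom, gate_is_open = TRUE)
  expect_equal(mv$Phi, numeric(n + 1))
  # wall squeeze upstream of a closed gate must not leak through it
  dV <- numeric(n); dV[10] <- 1e-7
  mv <- mixture_velocity(dV, numeric(n), V, geom, gate_is_open = FALSE)
  expect_equal(mv$Phi[geom$gate_face], 0)
  expect_equal(mv$Phi[1], 0)
  # compliance conserves antral volume: effective dVdt sums to zero upstream
  expect_equal(sum(mv$dVdt[seq_len(geom$gate_face - 1)]), 0, tolerance = 1e-22)
  # downstream of an open gate, flux accumulates the upstream imbalance
  mv2 <- mixture_velocity(dV, numeric(n), V, geom, gate_is_open = TRUE)
  expect_equal(mv2$Phi[n + 1], -sum(dV), tolerance = 1e-22)
})

test_that("discrete volume budget telescopes: boundary flux equals the sum of
           sources minus wall change", {
  geom <- gi_geometry()
  set.seed(3)
  dV <- rnorm(geom$n, 0, 1e-8)
  Q <- runif(geom$n, 0, 1e-9)
  V <- pi * geom$R0^2 * geom$dx
  mv <- mixture_velocity(dV, Q, V, geom, gate_is_open = TRUE)
  expect_equal(mv$Phi[geom$n + 1], sum(Q) - sum(dV), tolerance = 1e-12)
  # interior telescoping: Phi jump across each cell = Q - dV
  expect_equal(diff(mv$Phi), Q - dV, tolerance = 1e-12)
})

test_that("a uniform inert state with a still wall is invariant", {
  # no secretory regions, neutral water + particles: pH sits at the cap, so
  # nothing dissolves, reacts or moves (gravity off, waves off)
  us <- uniform_setup(region = 0L,
                      Y = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  sim <- gi_run(1, T = 2, config = us$config, geom = us$geom, init = us$init,
                output_dt = 1)
  expect_equal(sim$final$P, us$init$P, tolerance = 1e-12)
  expect_equal(sim$final$Cm, us$init$Cm, tolerance = 1e-12)
})

test_that("spatially uniform forcing: the 1D solver agrees cell-wise with the
           batch reactor", {
  us <- uniform_setup(region = 2L)
  n <- us$geom$n
  sim <- gi_run(1, T = 5, config = us$config, geom = us$geom, init = us$init,
                output_dt = 5)
  expect_equal(sim$substeps, 100)   # dt pinned at dt_max = 0.05
  st <- gi_batch_init(volume = n * us$Vcell, alpha = us$alpha, Y = us$Y,
                      config = us$config, scenario = 1, regions = 2)
  st <- gi_step_batch(st, 0.05, 100)
  bs <- gi_batch_summary(st)
  for (cell in c(1, n %/% 2, n)) {
    expect_equal(unname(sim$final$alpha[cell, ]), unname(bs$alpha),
                 tolerance = 1e-6)
    expect_equal(unname(sim$final$Y[cell, ]), unname(bs$Y),
                 tolerance = 1e-6)
  }
  # and the fields stay spatially uniform
  expect_lt(max(apply(sim$final$Y, 2, function(y) diff(range(y)))), 1e-9)
})

test_that("a passive tracer under full peristalsis is conserved up to the
           outlet flux", {
  # water-only contents with a tagged tracer blob; all wall sources off but
  # waves and gating active: pure advection-diffusion of the tracer
  cfg <- gi_config(numerics = list(dx = 4e-3))
  geom <- gi_geometry(cfg)
  geom$region[] <- 0L
  Vcell <- pi * wall_radius(geom$x, 0, cfg)^2 * geom$dx
  P <- cbind(1000 * Vcell, matrix(0, geom$n, 5))
  Cm <- matrix(0, geom$n, 10)
  Cm[, 10] <- P[, 1]
  Cm[10:20, 7] <- 1e-7
  Cm[10:20, 10] <- Cm[10:20, 10] - 1e-7
  sim <- gi_run(1, T = 20, config = cfg, geom = geom,
                init = list(Cm = Cm, P = P), output_dt = 5)
  expect_equal(sum(sim$final$Cm[, 7]) + sim$ledgers$evac_comp[7],
               sum(Cm[, 7]), tolerance = 1e-9)
  expect_lt(abs(sim$closure), 1e-9)
  expect_equal(sum(sim$ledgers$secreted), 0)
})

test_that("T = 0 echoes the initial state", {
  cfg <- gi_config(numerics = list(dx = 4e-3))
  sim <- gi_run(1, T = 0, config = cfg)
  geom <- gi_geometry(cfg)
  st <- make_initial_state(geom, cfg, 1)
  expect_equal(sim$final$P, st$P)
  expect_equal(nrow(sim$series), 1)
  expect_equal(sim$substeps, 0)
})

test_that("short scenario-1 run: ledgers close, fractions stay physical,
           outputs are finite", {
  sim <- cached_run(1, 36, dx = 4e-3)
  expect_lt(abs(sim$closure), 1e-8)
  expect_true(all(sim$final$alpha >= -1e-12 & sim$final$alpha <= 1 + 1e-12))
  expect_equal(rowSums(sim$final$alpha), rep(1, sim$geom$n), tolerance = 1e-8)
  expect_equal(rowSums(sim$final$Y), rep(1, sim$geom$n), tolerance = 1e-8)
  expect_true(all(is.finite(as.matrix(sim$series))))
  expect_true(sim$valid)   # clipped mass within tolerance
  expect_gt(sum(sim$ledgers$secreted), 0)
  # acid builds up in the stomach: mean pH falls below the water cap
  expect_lt(tail(sim$series$ph_stomach_mean, 1), 7)
})

test_that("halving the grid spacing changes the 306-s bin mass changes by
           less than 10%", {
  s2 <- cached_run(1, 306)              # default dx = 2 mm
  s1 <- cached_run(1, 306, dx = 1e-3)   # halved
  rel <- abs(s1$phase_change_pct[2:6] - s2$phase_change_pct[2:6]) /
    abs(s2$phase_change_pct[2:6])
  expect_lt(max(rel), 0.10)
})

test_that("re-running the same configuration is byte-identical
           (deterministic model, no RNG)", {
  cfg <- gi_config(numerics = list(dx = 4e-3))
  s1 <- gi_run(3, T = 10, config = cfg)
  s2 <- gi_run(3, T = 10, config = cfg)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$final$P, s2$final$P)
})
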