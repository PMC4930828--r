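test_that("baseline radius profile is positive and piecewise as designed", {
  cfg <- gi_config()
  g <- cfg$geometry
  x <- seq(0, g$antrum_length + g$pylorus_length + g$duodenum_length,
           by = 1e-3)
  r <- r0_profile(x, cfg)
  expect_true(all(r > 0))
  expect_equal(r[1], g$antrum_r_max)
  expect_equal(r0_profile(g$antrum_length, cfg), g$antrum_r_end)
  expect_equal(r0_profile(g$antrum_length + g$pylorus_length / 2, cfg),
               g$pylorus_radius)
  expect_equal(r[length(r)], g$duodenum_radius)
})

test_that("wall radius: zero motor functionality freezes the wall", {
  cfg <- gi_config()
  geom <- gi_geometry(cfg)
  for (t in c(0, 7.3, 25, 100)) {
    r <- wall_radius(geom$x, t, cfg, motor = 0)
    expect_equal(r[!geom$is_pylorus], geom$R0[!geom$is_pylorus])
  }
})

test_that("wave crest depth equals the amplitude and scales linearly with F", {
  cfg <- gi_config(waves = list(ramp = 1e-9))  # no envelope for this check
  wa <- cfg$waves$antral
  # crest of the first antral wave at t: center = speed * t; probe the center
  t <- 20
  xc <- wa$origin + wa$speed * t
  r1 <- wall_radius(xc, t, cfg, motor = 1)
  expect_equal(r0_profile(xc, cfg) - r1, wa$amplitude, tolerance = 1e-12)
  # half functionality gives exactly half the depth everywhere in the antrum
  x <- seq(0, 0.1, by = 1e-3)
  d1 <- r0_profile(x, cfg) - wall_radius(x, t, cfg, motor = 1)
  d5 <- r0_profile(x, cfg) - wall_radius(x, t, cfg, motor = 0.5)
  expect_equal(d5, d1 / 2, tolerance = 1e-12)
})

test_that("radius never drops below the floor", {
  cfg <- gi_config()
  geom <- gi_geometry(cfg)
  for (t in seq(0, 54, by = 0.5)) {
    expect_true(all(wall_radius(geom$x, t, cfg, motor = 1) >=
                      cfg$geometry$r_floor - 1e-15))
  }
})

test_that("pyloric gate has the 2/18 duty cycle and period 18", {
  cfg <- gi_config()
  tt <- seq(0, 18, by = 1e-3)
  open <- gate_open(tt, cfg)
  expect_equal(mean(open), 2 / 18, tolerance = 1e-3)
  expect_equal(gate_open(tt, cfg), gate_open(tt + 18, cfg))
  # open time over 306 s = 17 cycles x 2 s
  tt <- seq(0, 306, by = 1e-2)
  expect_equal(sum(gate_open(tt[-length(tt)], cfg)) * 1e-2, 34,
               tolerance = 0.1)
})

test_that("gate opening is synchronized with wave arrival at mid-antrum", {
  cfg <- gi_config()
  geom <- gi_geometry(cfg)
  mid <- cfg$geometry$antrum_length / 2
  for (k in 0:3) {
    t_arr <- mid / cfg$waves$antral$speed + k * cfg$gate$period
    expect_true(gate_open(t_arr, cfg))
    # a wave crest sits at mid-antrum: the wall there is contracted
    expect_lt(wall_radius(mid, t_arr, cfg),
              r0_profile(mid, cfg) - 0.9 * cfg$waves$antral$amplitude)
  }
})

test_that("cell volumes are pi R^2 dx and periodic wall motion is neutral", {
  cfg <- gi_config()
  geom <- gi_geometry(cfg)
  cv <- cell_volumes(0, geom, cfg)
  expect_equal(cv$V, pi * wall_radius(geom$x, 0, cfg)^2 * geom$dx)
  # no waves -> dV/dt = 0
  cfg0 <- gi_config(waves = list(antral = list(amplitude = 0),
                                 duodenal = list(amplitude = 0)))
  cv0 <- cell_volumes(13, gi_geometry(cfg0), cfg0)
  expect_equal(max(abs(cv0$dVdt)), 0)
  # total volume returns to itself after a whole number of wave periods once
  # the wave train is periodic (two LCM(18, 9) = 18 s cycles apart)
  t1 <- 90; t2 <- t1 + 18
  V1 <- sum(cell_volumes(t1, geom, cfg)$V)
  V2 <- sum(cell_volumes(t2, geom, cfg)$V)
  expect_equal(V1, V2, tolerance = 1e-10)
})

test_that("geometry table round-trips through the text file", {
  geom <- gi_geometry()
  path <- tempfile(fileext = ".tsv")
  write_geometry(geom, path)
  back <- read_geometry(path)
  expect_equal(back$R0, geom$R0, tolerance = 1e-10)
  expect_equal(back$region, geom$region)
  expect_equal(back$gravity, geom$gravity, tolerance = 1e-10)
  unlink(path)
})

test_that("regions partition the tract and the fill lies in the stomach", {
  geom <- gi_geometry()
  expect_true(all(geom$region %in% c(0L, 2L, 3L, 4L, 5L)))
  expect_true(all(which(geom$fill) <= sum(geom$antral)))
  expect_true(any(geom$region == 2), label = "acid region present")
  expect_true(all(diff(geom$x) > 0))
})
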