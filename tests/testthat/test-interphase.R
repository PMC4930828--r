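test_that("dissolution coefficient follows the acid power law with the
           alkaline clamp", {
  expect_equal(dissolution_coefficient(1), 2.72e-4 * 3.246, tolerance = 1e-12)
  expect_equal(dissolution_coefficient(1), 8.83e-4, tolerance = 1e-3)
  expect_equal(dissolution_coefficient(2), 2.72e-4 * 3.246 * 2^-2.092)
  expect_equal(dissolution_coefficient(2), 2.071e-4, tolerance = 1e-3)
  expect_equal(dissolution_coefficient(7.5), 0)
  expect_equal(dissolution_coefficient(7), 0)
  expect_error(dissolution_coefficient(0), "positive")
  # near the normal gastric acidity the modifier is ~1
  expect_equal(dissolution_coefficient(1.8) / 2.72e-4, 1, tolerance = 0.06)
})

test_that("particle-to-solution flux: surface scaling, composition split,
           terminal-bin exemption", {
  k <- 2.071e-4
  expect_equal(particle_to_solution_flux(0, 7e-4, k, 0.013), 0)
  expect_equal(particle_to_solution_flux(0.088, 7e-4, k, 0.013),
               0.013 * 6 * k * 0.088 / 7e-4)
  expect_equal(particle_to_solution_flux(0.088, 7e-4, k, 0.013),
               2.03e-3, tolerance = 1e-3)
  expect_equal(particle_to_solution_flux(0.088, 2e-4, k, 0.013,
                                         dissolvable = FALSE), 0)
  # composition closure: summed over components the flux is 6 k alpha / d
  beta <- gi_config()$particle$beta
  tot <- sum(particle_to_solution_flux(0.05, 1.7e-3, k, beta))
  expect_equal(tot, 6 * k * 0.05 / 1.7e-3, tolerance = 1e-12)
})

test_that("bin cascade flux matches the shrinking-sphere geometry", {
  k <- 2.071e-4
  expect_equal(bin_cascade_flux(0, 7e-4, 2e-4, k), 0)
  v <- bin_cascade_flux(0.088, 7e-4, 2e-4, k)
  expect_equal(v, 6 * (2e-4)^3 * k * 0.088 / (7e-4 * ((7e-4)^3 - (2e-4)^3)))
  expect_equal(v, 3.73e-3, tolerance = 1e-3)
  expect_equal(bin_cascade_flux(0.1, 2e-4, NA, k), 0)  # terminal bin
  expect_error(bin_cascade_flux(0.1, 2e-4, 7e-4, k), "d_j > d_next")
})

test_that("drag coefficient: Stokes limit, symmetry, Reynolds warning", {
  expect_equal(drag_coefficient(0.1, 0.9, 1e-3, NA, eta = 1e-3, rho = 1000,
                                slip = 0), 1620)
  expect_equal(drag_coefficient(0, 0.9, 1e-3, NA, eta = 1e-3, rho = 1000,
                                slip = 0.1, warn_re = FALSE), 0)
  # symmetry in the particle-particle form for arbitrary inputs
  set.seed(7)
  for (i in 1:20) {
    a <- runif(2, 0, 0.5); d <- runif(2, 1e-4, 4e-3); s <- runif(1, 0, 0.05)
    k1 <- drag_coefficient(a[1], a[2], d[1], d[2], eta = 1, rho = 1040,
                           slip = s, warn_re = FALSE)
    k2 <- drag_coefficient(a[2], a[1], d[2], d[1], eta = 1, rho = 1040,
                           slip = s, warn_re = FALSE)
    expect_equal(k1, k2, tolerance = 1e-12)
  }
  expect_warning(
    drag_coefficient(0.1, 0.9, 3.6e-3, NA, eta = 1e-3, rho = 1000, slip = 1),
    "Reynolds"
  )
})

test_that("terminal slip matches a brute-force bisection oracle", {
  # oracle: root of s (1 + 0.15 Re(s)^0.687) - drive = 0 on a sign bracket
  bisect_slip <- function(alpha1, d, rho_j, rho_mix, g_ax, eta1, rho1) {
    a1 <- max(alpha1, 0.05)
    drive <- (rho_j - rho_mix) * g_ax * d^2 / (18 * a1 * eta1)
    if (drive == 0) return(0)
    f <- function(s) s * (1 + 0.15 * (rho1 * abs(s) * d / eta1)^0.687) - drive
    lo <- min(0, drive); hi <- max(0, drive)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) * f(lo) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  num <- gi_config()$numerics
  num$slip_cap <- 10
  set.seed(11)
  for (i in 1:20) {
    alpha1 <- runif(1, 0.2, 1)
    d <- runif(1, 1e-4, 4e-3)
    rho_j <- runif(1, 1000, 1100)
    rho_mix <- runif(1, 995, 1050)
    g_ax <- runif(1, -9.81, 9.81)
    s <- slip_velocity(alpha1, d, rho_j, rho_mix, g_ax, 1e-3, 1000, num)
    s_or <- bisect_slip(alpha1, d, rho_j, rho_mix, g_ax, 1e-3, 1000)
    expect_lt(abs(s - s_or), 1e-8)   # absolute agreement in m/s
  }
})

test_that("slip: neutral buoyancy gives zero; settling sign; density
           monotonicity (scenario 6 slips less than scenario 1)", {
  num <- gi_config()$numerics
  expect_equal(slip_velocity(0.4, 1e-3, 1040, 1040, -4.9, numerics = num), 0)
  # denser than the mixture with gravity pointing toward the bulge: settles
  s1 <- slip_velocity(0.4, 7e-4, 1040, 1024, -4.9, numerics = num)
  expect_lt(s1, 0)
  s6 <- slip_velocity(0.4, 7e-4, 1005, 1002, -4.9, numerics = num)
  expect_lt(abs(s6), abs(s1))
})
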