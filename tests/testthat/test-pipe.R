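test_that("Poiseuille wall shear matches hand-evaluated anchor points", {
  mu <- 6.92e-4
  q <- 200e-6 / 60                      # 200 mL/min
  expect_equal(pipe_wall_shear(0, 2.5e-3, mu), 0)
  expect_equal(pipe_wall_shear(q, 2.5e-3, mu), 0.188, tolerance = 2e-3)
  # at fixed bulk velocity, tau = 4 mu U / R: doubling R halves tau
  U <- 0.2
  tau1 <- pipe_wall_shear(pi * 2.5e-3^2 * U, 2.5e-3, mu)
  tau2 <- pipe_wall_shear(pi * 5.0e-3^2 * U, 5.0e-3, mu)
  expect_equal(tau1, 2 * tau2)
  expect_error(pipe_wall_shear(q, 0, mu), "positive")
  expect_error(pipe_wall_shear(-q, 2.5e-3, mu), "non-negative")
})

test_that("bulk velocities reproduce the catheter and pipe figures", {
  q <- 200e-6 / 60
  expect_equal(bulk_velocity(q, 2.5e-3) * 100, 17, tolerance = 0.01)
  expect_equal(bulk_velocity(q, 4.5e-3) * 100, 5.2, tolerance = 0.02)
  expect_equal(bulk_velocity(1e-3 / 60, 1.25e-2) * 100, 3.4,
               tolerance = 0.01)
  expect_equal(bulk_velocity(0, 2.5e-3), 0)
  expect_error(bulk_velocity(q, -1), "positive")
})

test_that("Reynolds number and the 2100 laminar threshold behave", {
  r0 <- reynolds(0, 5e-3, water37)
  expect_equal(r0$reynolds, 0); expect_true(r0$laminar)
  f <- fluid_properties(993, 6.92e-4)
  r1 <- reynolds(0.17, 5e-3, f)
  expect_equal(r1$reynolds, 993 * 0.17 * 5e-3 / 6.92e-4, tolerance = 1e-12)
  expect_equal(r1$reynolds, 1220, tolerance = 0.01)
  expect_true(r1$laminar)
  # just over the threshold flips the flag
  u_star <- 2100 * f$mu / (f$rho * 5e-3)
  expect_true(reynolds(u_star * (1 - 1e-9), 5e-3, f)$laminar)
  expect_false(reynolds(u_star * (1 + 1e-9), 5e-3, f)$laminar)
})

test_that("shear/velocity/radius identity holds to rounding error", {
  set.seed(42)
  for (i in 1:25) {
    Q <- stats::runif(1, 1e-8, 1e-4)
    R <- stats::runif(1, 5e-4, 2e-2)
    mu <- stats::runif(1, 3e-4, 2e-3)
    lhs <- pipe_wall_shear(Q, R, mu)
    rhs <- 4 * mu * bulk_velocity(Q, R) / R
    expect_lt(abs(lhs - rhs) / lhs, 1e-12)
  }
  # monotonicity: increasing Q raises tau, increasing R lowers it
  expect_true(all(diff(pipe_wall_shear(seq(1e-6, 1e-5, length.out = 5),
                                       2e-3, 7e-4)) > 0))
  expect_true(all(diff(pipe_wall_shear(1e-6, seq(1e-3, 1e-2,
                                                 length.out = 5),
                                       7e-4)) < 0))
})

test_that("equivalence grid masks turbulence and unreachable shear", {
  # peaks span [0.05, 2.4] so the 0.188 N/m^2 reference cell is reachable
  map <- fake_shear_map(c(10, 30, 60), row_peaks = c(0.05, 2.4, 1.0),
                        row_avgs = c(0.01, 0.46, 0.2))
  g <- equivalence_grid(water37, velocities = c(0.05, 0.17, 2.5),
                        diameters = c(5e-3, 2.5e-2), map = map)
  # 17 cm/s through 5 mm: tau about 0.188, reachable and laminar
  expect_false(g$masked[2, 1])
  expect_equal(g$tau[2, 1], 4 * water37$mu * 0.17 / 2.5e-3)
  # turbulent corner (2.5 m/s through 2.5 cm) is masked regardless of tau
  expect_true(reynolds(2.5, 2.5e-2, water37)$reynolds > 2100)
  expect_true(g$masked[3, 2])

  # an all-zero map masks everything
  mz <- fake_shear_map(c(10, 30, 60), row_peaks = c(0, 0, 0),
                       row_avgs = c(0, 0, 0))
  gz <- equivalence_grid(water37, velocities = c(0.05, 0.17),
                         diameters = c(5e-3), map = mz)
  expect_true(all(gz$masked))

  # enlarging the achievable range never masks a previously unmasked cell
  bigger <- fake_shear_map(c(10, 30, 60), row_peaks = c(0.01, 5, 1),
                           row_avgs = c(0.01, 5, 1))
  gb <- equivalence_grid(water37, velocities = c(0.05, 0.17, 2.5),
                         diameters = c(5e-3, 2.5e-2), map = bigger)
  expect_true(all(gb$masked[!g$masked] == FALSE))
})

test_that("built-in scenarios carry the published diameters and flows", {
  sc <- builtin_scenarios()
  expect_named(sc, c("I", "II", "III", "IV"))
  expect_true(all(vapply(sc, function(s) all(s$diameters > 0), TRUE)))
  # region III: 200-400 mL/min through 5 mm spans about 17-34 cm/s
  u3 <- bulk_velocity(sc$III$flow_rates, 2.5e-3) * 100
  expect_equal(u3, c(17, 34), tolerance = 0.01)
  # region IV: 1 L/min through 1.0-2.5 cm gives 21 down to 3.4 cm/s
  u4 <- bulk_velocity(1e-3 / 60, sc$IV$diameters / 2) * 100
  expect_equal(round(u4, 1), c(21.2, 3.4))
  # the L/s reading is selectable but produces mains-scale velocities
  sc2 <- builtin_scenarios("L_per_s")
  expect_equal(bulk_velocity(sc2$IV$flow_rates[1], 1.25e-2),
               60 * bulk_velocity(sc$IV$flow_rates[1], 1.25e-2))
  # converters
  expect_equal(french_to_diameter(12), 4e-3)
  expect_equal(gauge_to_diameter(16), 1.19e-3)
  expect_error(gauge_to_diameter(99), "unsupported")
  expect_equal(scenario_velocity_range(sc$I), c(0.08, 0.60))
  expect_equal(scenario_velocity_range(sc$III)[1],
               bulk_velocity(200e-6 / 60, 4.5e-3))
})
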