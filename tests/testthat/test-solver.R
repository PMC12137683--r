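# grid helper for direct shallow_water_run scenarios
make_grid <- function(L, n) -L / 2 + (seq_len(n) - 0.5) * (L / n)

test_that("still level water under no rocking stays exactly at rest", {
  r <- shallow_water_run(0.08, rep(2.4e-3, 100), fluid = water37,
                         duration = 1, record_times = c(0.5, 1))
  expect_equal(max(abs(r$u)), 0)
  expect_equal(max(abs(r$tau)), 0)
  expect_equal(r$volume_drift, 0)
})

test_that("lake at rest on a fixed tilt is preserved to machine precision", {
  n <- 200; L <- 0.08
  x <- make_grid(L, n)
  for (th_deg in c(0.5, 4, 7)) {
    th <- th_deg * pi / 180
    b <- -x * tan(th)
    h0 <- pmax(0, (max(b) + 1.5e-3) - b)     # partially dry at the high end
    r <- shallow_water_run(L, h0, fluid = water37, duration = 1,
                           record_times = 1, motion = th)
    expect_lt(max(abs(r$u)), 1e-10)
    expect_lt(r$volume_drift, 1e-8)
  }
})

test_that("a fixed small tilt relaxes to pooled equilibrium", {
  r <- shallow_water_run(0.08, rep(2.4e-3, 200), fluid = water37,
                         duration = 30, record_times = 30,
                         motion = 0.5 * pi / 180)
  expect_lt(max(abs(r$u)), 1e-4)
  expect_lt(max(abs(r$tau)), 1e-4)
  # surface is level in the lab frame: h + b constant over wet cells
  x <- make_grid(0.08, 200)
  w_surf <- r$h[1, ] - x * tan(0.5 * pi / 180)
  expect_lt(diff(range(w_surf)), 2e-5)
})

test_that("inviscid dam break matches the Ritter rarefaction solution", {
  n <- 400; L <- 0.08; h0 <- 2e-3; g <- water37$gravity
  x <- make_grid(L, n)
  hi <- ifelse(x < 0, h0, 0)
  c0 <- sqrt(g * h0)
  tmax <- 0.25 * (L / 2) / c0               # well before any wall contact
  r <- shallow_water_run(L, hi, fluid = water37, duration = tmax,
                         record_times = tmax, frictionless = TRUE)
  xi <- x / tmax
  h_ritter <- ifelse(xi < -c0, h0,
                     ifelse(xi < 2 * c0, (2 * c0 - xi)^2 / (9 * g), 0))
  l1 <- sum(abs(r$h[1, ] - h_ritter)) / sum(h_ritter)
  expect_lt(l1, 0.02)
  expect_lt(r$volume_drift, 1e-8)
})

test_that("small surface pulses travel at sqrt(g h)", {
  L <- 1; n <- 500
  x <- make_grid(L, n)
  h0 <- 2e-3 + 2e-5 * exp(-(x / 0.02)^2)
  r <- shallow_water_run(L, h0, fluid = water37, duration = 3,
                         record_times = seq(1, 3, by = 0.25),
                         frictionless = TRUE)
  # track the right-going crest after the two half-pulses separate
  right <- x > 0.05
  crest <- apply(r$h, 1, function(hh) x[right][which.max(hh[right])])
  v <- unname(stats::coef(stats::lm(crest ~ r$t))[2])
  expect_equal(v, sqrt(water37$gravity * 2e-3), tolerance = 0.05)
})

test_that("volume is conserved to 1e-8 over twenty rocking periods", {
  cfg <- solver_config(n_cells = 200, spinup_periods = 19,
                       record_periods = 1)
  r <- simulate_rocking_flow(geom_default, 5e-6, profile_740, water37, cfg)
  expect_lt(r$diagnostics$volume_drift, 1e-8)
  # and per-sample recorded volume is flat too
  expect_lt(diff(range(r$volume)) / r$volume[1], 1e-8)
})

test_that("period-averaged shear map is mirror-symmetric about the pivot", {
  r <- simulate_rocking_flow(geom_default, 5e-6,
                             make_motion_profile(motion_settings(7, 30)),
                             water37, solver_config(n_cells = 400))
  pa <- period_average(r)
  expect_lt(max(abs(pa - rev(pa))) / max(pa), 0.02)
})

test_that("refining the grid converges the period-averaged shear map", {
  p <- make_motion_profile(motion_settings(7, 30))
  common_x <- seq(-0.039, 0.039, length.out = 50)
  avgs <- lapply(c(100, 200, 400), function(nn) {
    r <- simulate_rocking_flow(geom_default, 5e-6, p, water37,
                               solver_config(n_cells = nn))
    stats::approx(r$x, period_average(r), xout = common_x)$y
  })
  d <- vapply(1:2, function(i) sqrt(mean((avgs[[i]] - avgs[[i + 1]])^2)), 1)
  expect_true(all(diff(d) < 0))             # Richardson-style contraction
})

test_that("wall shear closure follows tau = 3 mu u / h on wet cells", {
  f <- fluid_properties(993, 6.92e-4)
  expect_equal(wall_shear(1e-3, 0.1, f), 0.2076, tolerance = 1e-12)
  expect_equal(wall_shear(1e-3, 0, f), 0)
  expect_equal(wall_shear(0.5e-3, 0.1, f), 2 * wall_shear(1e-3, 0.1, f))
  expect_equal(wall_shear(1e-3, -0.1, f), -wall_shear(1e-3, 0.1, f))
  expect_equal(wall_shear(1e-8, 0.1, f), 0)  # dry cell contract
  expect_error(wall_shear(-1e-3, 0.1, f), "non-negative")
})

test_that("simulation rejects invalid fill volumes and records dry zeros", {
  expect_error(simulate_rocking_flow(geom_default, 0, profile_740, water37,
                                     cfg_coarse), "fill_volume")
  expect_error(simulate_rocking_flow(geom_default, 30e-6, profile_740,
                                     water37, cfg_coarse), "fill_volume")
  r <- simulate_rocking_flow(geom_default, 5e-6, profile_740, water37,
                             cfg_coarse)
  dry <- r$h <= cfg_coarse$dry_threshold
  expect_true(all(r$tau[dry] == 0))
  expect_true(all(is.finite(r$tau)))
})
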