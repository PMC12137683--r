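test_that("front detection returns nothing for fully wet or dry fields", {
  tt <- seq(0, 1, by = 0.02)
  full <- list(x = seq(-0.04, 0.04, length.out = 50), t = tt,
               h = matrix(2e-3, length(tt), 50),
               config = list(dry_threshold = 1e-6))
  expect_length(detect_front(full), 0)
  dry <- full; dry$h[] <- 0
  expect_length(detect_front(dry), 0)
})

test_that("a constructed front moving at 0.2 m/s is recovered exactly", {
  st <- gen_moving_front_states(velocity = 0.2)
  tr <- detect_front(st)
  expect_gte(length(tr), 1)
  v <- coc_velocity(tr[[1]])
  expect_equal(v$velocity, 0.2, tolerance = 5e-3)
  expect_lt(v$se, 1e-3)
  # and leftward motion is labelled and signed accordingly
  stl <- gen_moving_front_states(velocity = -0.15)
  trl <- detect_front(stl)
  expect_equal(trl[[1]]$direction, "right-to-left")
  expect_equal(coc_velocity(trl[[1]])$velocity, -0.15, tolerance = 5e-3)
})

test_that("dam-break front position tracks the Ritter solution", {
  n <- 800; L <- 0.08; h0 <- 2e-3; g <- water37$gravity
  x <- -L / 2 + (seq_len(n) - 0.5) * (L / n)
  hi <- ifelse(x < -0.02, h0, 0)
  rt <- seq(0, 0.18, by = 0.002)
  r <- shallow_water_run(L, hi, fluid = water37, duration = max(rt),
                         record_times = rt, frictionless = TRUE,
                         dry_threshold = 1e-8)
  rec <- list(h = r$h, t = r$t, x = r$x,
              config = list(dry_threshold = 1e-8))
  tr <- detect_front(rec, depth_threshold = 1e-7)
  expect_gte(length(tr), 1)
  keep <- tr[[1]]$position > 0 & tr[[1]]$position < 0.03
  v <- unname(stats::coef(stats::lm(tr[[1]]$position[keep] ~
                                      tr[[1]]$t[keep]))[2])
  # the wet-front contour converges a few percent below the analytic dry
  # tip 2*sqrt(g*h0) (the h -> 0 tip outruns any finite-depth contour)
  expect_equal(v, 2 * sqrt(g * h0), tolerance = 0.10)
})

test_that("CoC velocity fit matches the closed-form OLS oracle", {
  # noiseless trace: exact slope, zero standard error
  tt <- seq(0, 0.4, by = 0.02)
  tr <- wavefront_trace(tt, 0.15 * tt - 0.03)
  v <- coc_velocity(tr)
  expect_equal(v$velocity, 0.15)
  expect_lt(v$se, 1e-12)

  # noisy traces: reported SE tracks sigma / sqrt(Sxx), and the 3-SE
  # interval covers the truth for (nearly) all seeds
  sigma <- 5e-4
  inside <- vapply(1:10, function(s) {
    tr2 <- gen_wavefront_trace(0.20, sigma = sigma, seed = s)
    v2 <- coc_velocity(tr2)
    keep <- abs(tr2$position) <= 0.02
    sxx <- sum((tr2$t[keep] - mean(tr2$t[keep]))^2)
    se_theory <- sigma / sqrt(sxx)
    expect_equal(v2$se, se_theory, tolerance = 0.6)  # estimated sigma
    abs(v2$velocity - 0.20) < 3 * se_theory
  }, TRUE)
  expect_gte(sum(inside), 9)

  # too few points inside the window is an error, not a guess
  tr3 <- wavefront_trace(c(0, 0.1, 0.2), c(0.025, 0.03, 0.035))
  expect_error(coc_velocity(tr3), "within")
})

test_that("velocity recovery is unbiased across the speed range", {
  # precision matching a sub-millimetre front localisation at 50 Hz
  speeds <- seq(0.05, 0.35, by = 0.05)
  err <- vapply(seq_along(speeds), function(i) {
    tr <- gen_wavefront_trace(speeds[i], sigma = 1.5e-4, seed = 100 + i)
    coc_velocity(tr)$velocity - speeds[i]
  }, 1)
  expect_lt(mean(abs(err)), 0.005)
})

test_that("simulated CoC wavefront velocity rises with speed to resonance", {
  vs <- vapply(c(20, 30, 40), function(sp) {
    p <- make_motion_profile(motion_settings(7, sp))
    r <- simulate_rocking_flow(geom_default, 9e-6, p, water37,
                               solver_config(n_cells = 400,
                                             record_rate = 200))
    tr <- detect_front(r, depth_threshold = 0.7 * fill_depth(9e-6))
    stats::median(abs(vapply(tr, function(x) coc_velocity(x)$velocity, 1)))
  }, 1)
  expect_true(all(diff(vs) > 0))
  # and the values track the resonance-formula scale (within a few cm/s)
  expect_equal(vs * 100, resonance_velocity(c(20, 30, 40)) * 100,
               tolerance = 0.25)
})

test_that("box statistics follow the linear-interpolation quartile rule", {
  b <- box_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 5)

  b2 <- box_stats(c(1, 1, 1, 1, 100))
  expect_equal(b2$outliers, 100)          # IQR = 0: any deviation is out
  expect_equal(b2$whisker_high, 1)

  b3 <- box_stats(7)
  expect_equal(b3$median, 7)
  expect_equal(b3$whisker_low, b3$whisker_high)
  expect_error(box_stats(numeric(0)), "at least one")
})

test_that("trace constructor validates ordering and lengths", {
  expect_error(wavefront_trace(c(0, 0.1, 0.1), c(1, 2, 3)), "increasing")
  expect_error(wavefront_trace(c(0, 0.1), c(1, 2, 3)), "lengths")
})
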