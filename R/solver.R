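#' Numerical configuration of the shallow-water solver
#'
#' @param n_cells Number of finite-volume cells along the channel
#'   (at least 50; default 400).
#' @param cfl CFL number for the adaptive time step, in (0, 1); default 0.4.
#' @param dry_threshold Depth below which a cell is treated as dry, metres
#'   (default 1e-6).
#' @param spinup_periods Rocking periods simulated before recording starts,
#'   so the flow is fully developed (default 5).
#' @param record_periods Rocking periods recorded after spin-up (default 1).
#' @param record_rate Output sampling rate in Hz (default 1000).
#' @param include_euler_forcing Include the rotating-frame centrifugal/Euler
#'   momentum sources. At device speeds these are at most a couple of percent
#'   of gravity, so the default is `FALSE`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_cells = 400, cfl = 0.4, dry_threshold = 1e-6,
                          spinup_periods = 5, record_periods = 1,
                          record_rate = 1000, include_euler_forcing = FALSE) {
  if (n_cells < 50) stop("n_cells must be at least 50", call. = FALSE)
  if (cfl <= 0 || cfl >= 1) stop("cfl must be in (0, 1)", call. = FALSE)
  if (dry_threshold <= 0) stop("dry_threshold must be positive", call. = FALSE)
  if (spinup_periods < 0 || record_periods < 1)
    stop("spinup_periods must be >= 0 and record_periods >= 1", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), cfl = cfl,
                 dry_threshold = dry_threshold,
                 spinup_periods = spinup_periods,
                 record_periods = record_periods,
                 record_rate = record_rate,
                 include_euler_forcing = isTRUE(include_euler_forcing)),
            class = "solver_config")
}

#' Low-level shallow-water run on a (possibly tilting) channel
#'
#' Advances the 1D shallow-water equations on the channel floor with
#' reflective walls at both ends, wetting/drying, and the laminar wall
#' friction closure. The tilt can be absent, fixed, or the periodic rocking
#' profile; in the rocking case the equations are solved in the co-rotating
#' frame with the bed-parallel gravity component `g sin(theta)` and reduced
#' normal gravity `g cos(theta)`. Mainly useful for validation runs
#' (dam break, gravity-wave pulses, lake at rest); use
#' [simulate_rocking_flow()] for the full device simulation.
#'
#' @param L Channel length, metres.
#' @param h_init,q_init Initial depth (m) and discharge (m^2/s) per cell;
#'   lengths define `n_cells`.
#' @param fluid A [fluid_properties()] object; pass `frictionless = TRUE`
#'   for an inviscid run.
#' @param duration Simulated time, seconds.
#' @param record_times Output sample times (s), sorted, within
#'   `[0, duration]`.
#' @param motion `NULL` for no tilt, a single number for a fixed tilt in
#'   radians, or a [make_motion_profile()] object.
#' @param cfl,dry_threshold,include_euler_forcing See [solver_config()].
#' @param frictionless Drop the laminar friction term (inviscid run).
#' @return A list with `x`, `t`, and matrices `h`, `u`, `tau`
#'   (time by position), the tilt `theta` per sample, `volume` per sample,
#'   and solver diagnostics `n_steps`, `dt_min`, `volume_drift`.
#' @export
shallow_water_run <- function(L, h_init, q_init = rep(0, length(h_init)),
                              fluid = water_properties(37),
                              duration, record_times,
                              motion = NULL, cfl = 0.4,
                              dry_threshold = 1e-6,
                              include_euler_forcing = FALSE,
                              frictionless = FALSE) {
  stopifnot(inherits(fluid, "fluid_properties"))
  n <- length(h_init)
  if (length(q_init) != n) stop("h_init and q_init lengths differ",
                                call. = FALSE)
  if (any(h_init < 0)) stop("initial depths must be non-negative",
                            call. = FALSE)
  mode <- 0L; theta_fixed <- 0; alpha <- 0; omega <- 1; t_rev <- 0; period <- 1
  if (inherits(motion, "motion_profile")) {
    mode <- 2L
    alpha <- motion$alpha_rad; omega <- motion$omega_rad
    t_rev <- motion$t_rev; period <- motion$period
  } else if (is.numeric(motion) && length(motion) == 1) {
    mode <- 1L; theta_fixed <- motion
  } else if (!is.null(motion)) {
    stop("motion must be NULL, a fixed tilt (rad) or a motion_profile",
         call. = FALSE)
  }
  mu <- if (frictionless) 0 else fluid$mu
  res <- swe_core(n, L, as.numeric(h_init), as.numeric(q_init),
                  fluid$gravity, fluid$rho, mu, cfl, dry_threshold,
                  mode, theta_fixed, alpha, omega, t_rev, period,
                  duration, as.numeric(record_times),
                  include_euler_forcing)
  res
}

#' Simulate free-surface flow in a rocking well
#'
#' Runs the shallow-water model of one culture-plate well on the rocking
#' platform and records the wall shear stress on the channel floor. The run
#' starts from fluid at rest pooled under the initial tilt `theta(0)`,
#' advances `spinup_periods` rocking periods so the flow is fully developed,
#' then records depth, velocity and wall shear stress for `record_periods`
#' periods at `record_rate` Hz.
#'
#' Wall shear stress uses the laminar parabolic-profile closure
#' `tau = 3 mu u / h` (zero on dry cells), the standard thin-film result for
#' depth-averaged velocity `u`.
#'
#' @param geom A [well_geometry()].
#' @param fill_volume Fill volume in cubic metres, in `(0, capacity)`.
#' @param profile A [make_motion_profile()] object.
#' @param fluid A [fluid_properties()] object, e.g. [water_properties()].
#' @param config A [solver_config()].
#' @return An object of class `shear_record`: list with positions `x` (m),
#'   sample times `t` (s, starting at the end of spin-up), matrices `tau`
#'   (N/m^2), `h` (m), `u` (m/s) of dimension time by position, tilt `theta`
#'   (rad) per sample, and metadata (`fill_volume`, `profile`, `fluid`,
#'   `config`, diagnostics).
#' @examples
#' \donttest{
#' rec <- simulate_rocking_flow(
#'   well_geometry(), 5e-6,
#'   make_motion_profile(motion_settings(7, 40)),
#'   water_properties(37),
#'   solver_config(n_cells = 100, spinup_periods = 2))
#' max(abs(rec$tau))
#' }
#' @export
simulate_rocking_flow <- function(geom = well_geometry(),
                                  fill_volume = 5e-6,
                                  profile = make_motion_profile(),
                                  fluid = water_properties(37),
                                  config = solver_config()) {
  stopifnot(inherits(geom, "well_geometry"),
            inherits(profile, "motion_profile"),
            inherits(fluid, "fluid_properties"),
            inherits(config, "solver_config"))
  if (fill_volume <= 0 || fill_volume > geom$capacity)
    stop("fill_volume must be in (0, capacity]", call. = FALSE)
  n <- config$n_cells
  dx <- geom$length / n
  x <- -geom$length / 2 + (seq_len(n) - 0.5) * dx
  vol_per_width <- fill_volume / geom$width
  theta0 <- profile$theta(0)
  h0 <- pooled_depth_profile(x, dx, theta0, vol_per_width)

  t_start <- config$spinup_periods * profile$period
  n_rec <- ceiling(config$record_periods * profile$period *
                     config$record_rate)
  record_times <- t_start + (0:n_rec) / config$record_rate
  t_end <- max(record_times)

  res <- shallow_water_run(
    L = geom$length, h_init = h0, fluid = fluid,
    duration = t_end, record_times = record_times,
    motion = profile, cfl = config$cfl,
    dry_threshold = config$dry_threshold,
    include_euler_forcing = config$include_euler_forcing)

  structure(list(
    x = res$x, t = res$t - t_start, tau = res$tau, h = res$h, u = res$u,
    theta = res$theta, volume = res$volume,
    fill_volume = fill_volume, geom = geom, profile = profile,
    fluid = fluid, config = config,
    diagnostics = list(n_steps = res$n_steps, dt_min = res$dt_min,
                       volume_drift = res$volume_drift)),
    class = "shear_record")
}

#' @export
print.shear_record <- function(x, ...) {
  cat(sprintf(
    paste0("shear_record: %d samples x %d positions, fill %.1f mL, ",
           "%g deg/s at +/-%g deg\n  peak |tau| %.3g N/m^2, ",
           "volume drift %.1e\n"),
    length(x$t), length(x$x), x$fill_volume * 1e6,
    x$profile$settings$max_speed, x$profile$settings$max_angle,
    max(abs(x$tau)), x$diagnostics$volume_drift))
  invisible(x)
}

#' Laminar wall shear stress from depth and depth-averaged velocity
#'
#' Parabolic-profile (thin-film Poiseuille) closure: `tau = 3 mu u / h` on
#' wet cells, zero where the depth is at or below the dry threshold. The sign
#' follows the velocity.
#'
#' @param h Depth in metres (vectorised).
#' @param u Depth-averaged velocity in m/s.
#' @param fluid A [fluid_properties()] object.
#' @param dry_threshold Depth below which the cell counts as dry (m).
#' @return Wall shear stress in N/m^2.
#' @examples
#' wall_shear(1e-3, 0.1, fluid_properties(993, 6.92e-4)) # 0.2076
#' @export
wall_shear <- function(h, u, fluid, dry_threshold = 1e-6) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(h < 0)) stop("depth must be non-negative", call. = FALSE)
  ifelse(h > dry_threshold, 3 * fluid$mu * u / h, 0)
}

# Depth profile of fluid at rest in the co-rotating frame under tilt theta:
# free surface flat in the lab frame, i.e. w = h + b constant over the wet
# region with b(x) = -x tan(theta). Solves for the surface level matching the
# volume per unit width by bisection (monotone in w).
pooled_depth_profile <- function(x, dx, theta, vol_per_width) {
  b <- -x * tan(theta)
  vol_at <- function(w) sum(pmax(0, w - b)) * dx
  lo <- min(b)
  hi <- max(b) + vol_per_width / (length(x) * dx) + max(b) - min(b) + 1
  w <- stats::uniroot(function(w) vol_at(w) - vol_per_width,
                      lower = lo, upper = hi, tol = 1e-15)$root
  pmax(0, w - b)
}
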