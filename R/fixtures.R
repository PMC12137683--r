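#' Synthetic wavefront position trace
#'
#' Emulates a camera-based wavefront recording: positions advancing at a
#' constant true velocity, sampled at a fixed frame rate (default 50 Hz, a
#' typical camera setting), with Gaussian position noise. The trace spans at
#' least the +/- 2 cm fit window around the channel centre.
#'
#' @param velocity True front velocity in m/s (nonzero; sign sets the
#'   direction).
#' @param sigma Gaussian position noise standard deviation, metres
#'   (default 0.5 mm).
#' @param rate Sampling rate in Hz (default 50).
#' @param span Half-extent of the trace around CoC, metres (default 0.03;
#'   must cover the 2 cm fit window).
#' @param seed Integer RNG seed; recorded in the trace metadata.
#' @return A [wavefront_trace()] with metadata `velocity`, `sigma`, `rate`,
#'   `seed`.
#' @export
gen_wavefront_trace <- function(velocity, sigma = 5e-4, rate = 50,
                                span = 0.03, seed = 1234) {
  if (!is.numeric(velocity) || velocity == 0)
    stop("true velocity must be nonzero", call. = FALSE)
  if (sigma < 0 || rate <= 0) stop("sigma >= 0 and rate > 0 required",
                                   call. = FALSE)
  if (span < 0.02)
    stop("trace span shorter than the 2 cm fit window", call. = FALSE)
  t_half <- span / abs(velocity)
  tt <- seq(0, 2 * t_half, by = 1 / rate)
  pos0 <- -sign(velocity) * span + velocity * tt
  pos <- pos0 + with_local_seed(seed, stats::rnorm(length(tt), sd = sigma))
  wavefront_trace(
    tt, pos,
    direction = if (velocity > 0) "left-to-right" else "right-to-left",
    meta = list(velocity = velocity, sigma = sigma, rate = rate,
                seed = seed))
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic noisy temperature step-response trace
#'
#' Runs [simulate_step_response()] and adds independent Gaussian sensor
#' noise to both temperature channels, emulating logged thermistor data for
#' plant-parameter fitting tests.
#'
#' @param plant A [thermal_plant()].
#' @param gains A [pid_gains()].
#' @param setpoint Target temperature (degC).
#' @param duration Simulated time (s).
#' @param sigma Sensor noise standard deviation (degC, default 0.05).
#' @param seed Integer RNG seed.
#' @param ... Passed to [simulate_step_response()].
#' @return A `thermal_trace` with noise added; metadata attributes `sigma`
#'   and `seed`.
#' @export
gen_temperature_trace <- function(plant = thermal_plant(),
                                  gains = pid_gains(),
                                  setpoint = 37, duration = 1800,
                                  sigma = 0.05, seed = 1234, ...) {
  tr <- simulate_step_response(plant, gains, setpoint, duration, ...)
  noise <- with_local_seed(seed, stats::rnorm(2 * nrow(tr), sd = sigma))
  tr$T_plate_C <- tr$T_plate_C + noise[seq_len(nrow(tr))]
  tr$T_water_C <- tr$T_water_C + noise[nrow(tr) + seq_len(nrow(tr))]
  attr(tr, "sigma") <- sigma
  attr(tr, "seed") <- seed
  tr
}

#' Synthetic shear-stress record with known summary statistics
#'
#' Builds a `shear_record`-compatible object from constructed waveforms so
#' the analysis stages can be tested against exact hand-computable answers.
#'
#' @param kind `"pulse"` (a single rectangular pulse per period at every
#'   position), `"square"` (alternating +/- amplitude), `"constant"`, or
#'   `"dry"` (all zero).
#' @param amplitude Shear amplitude in N/m^2.
#' @param duty Fraction of the period the pulse is on (for `"pulse"`).
#' @param period Rocking period in seconds.
#' @param rate Sampling rate in Hz (default 1000).
#' @param n_positions Number of channel positions.
#' @param L Channel length in metres.
#' @return A list shaped like a `shear_record` (`x`, `t`, `tau`, `h`, `u`,
#'   `profile` with the matching `period`), class `shear_record`.
#' @export
gen_shear_record <- function(kind = c("pulse", "square", "constant", "dry"),
                             amplitude = 2, duty = 0.1, period = 0.7,
                             rate = 1000, n_positions = 20, L = 0.08) {
  kind <- match.arg(kind)
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]", call. = FALSE)
  tt <- seq(0, period, by = 1 / rate)
  phase <- (tt %% period) / period
  wave <- switch(kind,
    pulse = amplitude * (phase < duty),
    square = amplitude * ifelse(phase < 0.5, 1, -1),
    constant = rep(amplitude, length(tt)),
    dry = rep(0, length(tt)))
  tau <- matrix(rep(wave, n_positions), ncol = n_positions)
  dx <- L / n_positions
  x <- -L / 2 + (seq_len(n_positions) - 0.5) * dx
  h <- matrix(ifelse(kind == "dry", 0, 1e-3), nrow = length(tt),
              ncol = n_positions)
  structure(list(
    x = x, t = tt, tau = tau, h = h, u = tau, theta = rep(0, length(tt)),
    profile = list(period = period),
    config = list(dry_threshold = 1e-6),
    meta = list(kind = kind, amplitude = amplitude, duty = duty)),
    class = "shear_record")
}

#' Synthetic depth-field record with a front moving at constant speed
#'
#' A wet region whose right edge advances at a prescribed velocity across
#' the channel; used to validate [detect_front()] and [coc_velocity()]
#' against a known truth.
#'
#' @param velocity Front velocity in m/s (positive: left to right).
#' @param L Channel length (m).
#' @param n_cells Grid cells.
#' @param rate Sampling rate (Hz).
#' @param depth Wet depth (m).
#' @return A `shear_record`-shaped list with the moving-front depth field.
#' @export
gen_moving_front_states <- function(velocity = 0.2, L = 0.08, n_cells = 200,
                                    rate = 50, depth = 2e-3) {
  if (velocity == 0) stop("velocity must be nonzero", call. = FALSE)
  dx <- L / n_cells
  x <- -L / 2 + (seq_len(n_cells) - 0.5) * dx
  x0 <- if (velocity > 0) -0.35 * L else 0.35 * L
  t_cross <- 0.7 * L / abs(velocity)
  tt <- seq(0, t_cross, by = 1 / rate)
  h <- t(vapply(tt, function(ti) {
    front <- x0 + velocity * ti
    if (velocity > 0) ifelse(x < front, depth, 0)
    else ifelse(x > front, depth, 0)
  }, numeric(n_cells)))
  structure(list(x = x, t = tt, h = h, tau = h * 0, u = h * 0,
                 theta = rep(0, length(tt)),
                 profile = list(period = t_cross),
                 config = list(dry_threshold = 1e-6),
                 meta = list(velocity = velocity)),
            class = "shear_record")
}
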