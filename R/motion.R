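#' Rocker motion settings
#'
#' User-facing settings of the seesaw rocker: maximum tilt angle, maximum
#' angular speed and (optionally) maximum angular acceleration of the stepper
#' drive. The device accepts angles of 1--19 degrees and speeds of
#' 1--99 degrees per second.
#'
#' @param max_angle Maximum rocking angle alpha in degrees (amplitude of the
#'   tilt), in `[1, 19]`.
#' @param max_speed Maximum rocking speed omega in degrees per second, in
#'   `[1, 99]`.
#' @param max_accel Maximum angular acceleration in degrees per second squared;
#'   `Inf` (the default) means instantaneous reversal at the end stops.
#' @return An object of class `motion_settings`.
#' @export
motion_settings <- function(max_angle = 7, max_speed = 40, max_accel = Inf) {
  if (!is.numeric(max_angle) || max_angle < 1 || max_angle > 19)
    stop("max_angle must be in [1, 19] degrees", call. = FALSE)
  if (!is.numeric(max_speed) || max_speed < 1 || max_speed > 99)
    stop("max_speed must be in [1, 99] degrees per second", call. = FALSE)
  if (!is.numeric(max_accel) || max_accel <= 0)
    stop("max_accel must be positive (Inf for instantaneous reversal)",
         call. = FALSE)
  structure(list(max_angle = max_angle, max_speed = max_speed,
                 max_accel = max_accel),
            class = "motion_settings")
}

#' Periodic seesaw tilt profile
#'
#' Builds the periodic tilt trajectory theta(t) implied by the rocker
#' settings: a triangular wave between `+alpha` and `-alpha` traversed at
#' constant speed `omega`, with acceleration-limited reversals at the end
#' stops when `max_accel` is finite. Each reversal takes
#' `2*omega/max_accel` seconds and the full period is
#' `T = 4*alpha/omega + 2*omega/max_accel`; with unlimited acceleration
#' `T = 4*alpha/omega` exactly. The phase convention is `theta(0) = +alpha`
#' (full clockwise tilt, right end of the channel down).
#'
#' @param settings A [motion_settings()].
#' @return An object of class `motion_profile` with elements `period` (s),
#'   the vectorised functions `theta(t)`, `theta_dot(t)`, `theta_ddot(t)`
#'   (radians, rad/s, rad/s^2), the amplitude `alpha_rad`, cruise speed
#'   `omega_rad`, reversal duration `t_rev` (s) and the originating
#'   `settings`.
#' @examples
#' p <- make_motion_profile(motion_settings(max_angle = 7, max_speed = 40))
#' p$period # 0.7 s
#' @export
make_motion_profile <- function(settings = motion_settings()) {
  stopifnot(inherits(settings, "motion_settings"))
  deg <- pi / 180
  alpha <- settings$max_angle * deg
  omega <- settings$max_speed * deg
  if (is.finite(settings$max_accel)) {
    a <- settings$max_accel * deg
    if (a < omega^2 / (2 * alpha))
      stop(paste0("max_accel too small to reach max_speed within the tilt ",
                  "amplitude; need at least ",
                  format(settings$max_speed^2 / (2 * settings$max_angle)),
                  " deg/s^2"), call. = FALSE)
    t_rev <- 2 * omega / a
  } else {
    t_rev <- 0
  }
  period <- 4 * alpha / omega + t_rev
  theta_c <- alpha - omega * t_rev / 4    # tilt where the cruise phase starts
  t_c <- 2 * theta_c / omega              # duration of one cruise traverse

  eval_profile <- function(t, what) {
    s <- t %% period
    t1 <- t_rev / 2
    t2 <- t1 + t_c
    t3 <- t2 + t_rev
    t4 <- t3 + t_c
    th <- thd <- thdd <- numeric(length(s))
    a <- if (t_rev > 0) 2 * omega / t_rev else 0
    seg1 <- s < t1                       # leaving +alpha
    seg2 <- s >= t1 & s < t2             # cruise down
    seg3 <- s >= t2 & s < t3             # reversal through -alpha
    seg4 <- s >= t3 & s < t4             # cruise up
    seg5 <- s >= t4                      # approach to +alpha
    th[seg1] <- alpha - 0.5 * a * s[seg1]^2
    thd[seg1] <- -a * s[seg1]
    thdd[seg1] <- -a
    th[seg2] <- theta_c - omega * (s[seg2] - t1)
    thd[seg2] <- -omega
    u3 <- s[seg3] - t2
    th[seg3] <- -theta_c - omega * u3 + 0.5 * a * u3^2
    thd[seg3] <- -omega + a * u3
    thdd[seg3] <- a
    th[seg4] <- -theta_c + omega * (s[seg4] - t3)
    thd[seg4] <- omega
    u5 <- s[seg5] - t4
    th[seg5] <- theta_c + omega * u5 - 0.5 * a * u5^2
    thd[seg5] <- omega - a * u5
    thdd[seg5] <- -a
    switch(what, theta = th, theta_dot = thd, theta_ddot = thdd)
  }

  structure(list(
    period = period,
    theta = function(t) eval_profile(t, "theta"),
    theta_dot = function(t) eval_profile(t, "theta_dot"),
    theta_ddot = function(t) eval_profile(t, "theta_ddot"),
    alpha_rad = alpha, omega_rad = omega, t_rev = t_rev,
    settings = settings), class = "motion_profile")
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf(
    "motion_profile: +/-%g deg at %g deg/s, period %.3f s%s\n",
    x$settings$max_angle, x$settings$max_speed, x$period,
    if (x$t_rev > 0) sprintf(" (reversals %.3f s)", x$t_rev) else ""))
  invisible(x)
}

#' Convert rocking speed to revolutions per minute
#'
#' A full rocking period sweeps `4 * alpha` degrees, so the equivalent
#' rotational rate is `omega * 60 / (4 * alpha)` RPM. At the reference
#' amplitude of 7 degrees the conversion factor is `60 / 28 = 2.143`.
#'
#' @param omega Rocking speed in degrees per second.
#' @param alpha Maximum rocking angle in degrees; must be positive.
#' @return Equivalent rate in revolutions per minute.
#' @examples
#' rocking_speed_to_rpm(40, 7) # 85.7 RPM
#' @export
rocking_speed_to_rpm <- function(omega, alpha = 7) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("alpha must be positive", call. = FALSE)
  omega * 60 / (4 * alpha)
}

#' Wavefront velocity required for rocking resonance
#'
#' The travelling wavefront reinforces the rocking action when it returns in
#' phase with the tilt reversal, which happens at the wavefront velocity
#' `nu = omega * L / (2 * alpha)`: the front must traverse the channel length
#' L in the half-period `2 * alpha / omega`. Rocking speeds of 30, 40 and
#' 50 deg/s on an 8 cm channel at 7 degrees amplitude give 17, 23 and
#' 29 cm/s.
#'
#' @param omega Rocking speed in degrees per second.
#' @param L Channel length in metres.
#' @param alpha Maximum rocking angle in degrees; must be positive.
#' @return Resonant wavefront velocity in metres per second.
#' @examples
#' resonance_velocity(30, 0.08, 7) * 100 # about 17 cm/s
#' @export
resonance_velocity <- function(omega, L = 0.08, alpha = 7) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("alpha must be positive", call. = FALSE)
  if (!is.numeric(L) || any(L <= 0))
    stop("L must be positive", call. = FALSE)
  omega * L / (2 * alpha)
}
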