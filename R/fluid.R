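#' Fluid properties container
#'
#' @param rho Density in kg/m^3.
#' @param mu Dynamic viscosity in Pa s.
#' @param temperature Temperature in degrees Celsius (informational).
#' @param gravity Gravitational acceleration in m/s^2.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho, mu, temperature = NA_real_, gravity = 9.81) {
  if (!is.numeric(rho) || rho <= 0) stop("rho must be positive", call. = FALSE)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive", call. = FALSE)
  structure(list(rho = rho, mu = mu, temperature = temperature,
                 gravity = gravity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("fluid_properties: rho = %.1f kg/m^3, mu = %.3g Pa.s%s\n",
              x$rho, x$mu,
              if (is.na(x$temperature)) "" else
                sprintf(" (%.1f degC)", x$temperature)))
  invisible(x)
}

#' Properties of liquid water at a given temperature
#'
#' Density from the Kell (1975) polynomial fit and dynamic viscosity from the
#' Vogel correlation `mu = 2.414e-5 * 10^(247.8 / (T_K - 140))`. Both are
#' accurate to well under a percent across the liquid range at atmospheric
#' pressure. At 37 degrees Celsius this gives rho of about 993 kg/m^3 and mu
#' of about 6.9e-4 Pa s.
#'
#' @param temperature Temperature in degrees Celsius, strictly between 0
#'   and 100.
#' @param gravity Gravitational acceleration in m/s^2.
#' @return A [fluid_properties()] object.
#' @examples
#' water_properties(37)
#' @export
water_properties <- function(temperature = 37, gravity = 9.81) {
  if (!is.numeric(temperature) || temperature <= 0 || temperature >= 100)
    stop("temperature must be in the liquid range (0, 100) degC",
         call. = FALSE)
  t <- temperature
  rho <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
            46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
            280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
  mu <- 2.414e-5 * 10^(247.8 / (t + 273.15 - 140))
  fluid_properties(rho = rho, mu = mu, temperature = t, gravity = gravity)
}
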