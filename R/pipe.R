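#' Laminar pipe-flow wall shear stress
#'
#' Poiseuille result for fully developed laminar flow in a circular pipe:
#' `tau = 4 mu Q / (pi R^3)`, with `Q = pi R^2 U_mean` the volumetric flow
#' rate. Used to translate rocker shear output into equivalent real-world
#' pipe scenarios.
#'
#' @param Q Volumetric flow rate in m^3/s (non-negative).
#' @param R Pipe radius in metres (positive).
#' @param mu Dynamic viscosity in Pa s.
#' @return Wall shear stress in N/m^2.
#' @examples
#' # 200 mL/min through a 5 mm line of water at 37 degC
#' pipe_wall_shear(200e-6 / 60, 2.5e-3, water_properties(37)$mu)
#' @export
pipe_wall_shear <- function(Q, R, mu) {
  if (any(R <= 0)) stop("pipe radius must be positive", call. = FALSE)
  if (any(Q < 0)) stop("flow rate must be non-negative", call. = FALSE)
  4 * mu * Q / (pi * R^3)
}

#' Bulk (mean) velocity in a circular pipe
#'
#' @inheritParams pipe_wall_shear
#' @return Bulk velocity `U = Q / (pi R^2)` in m/s.
#' @examples
#' bulk_velocity(200e-6 / 60, 2.5e-3) * 100 # about 17 cm/s
#' @export
bulk_velocity <- function(Q, R) {
  if (any(R <= 0)) stop("pipe radius must be positive", call. = FALSE)
  Q / (pi * R^2)
}

#' Reynolds number and laminar flag for pipe flow
#'
#' `Re = rho U d / mu`; the flow is treated as laminar up to the
#' conventional transition value of 2100.
#'
#' @param U Bulk velocity in m/s.
#' @param d Pipe diameter in metres.
#' @param fluid A [fluid_properties()] object.
#' @param transition Transition Reynolds number (default 2100).
#' @return A list with `reynolds` and logical `laminar`.
#' @export
reynolds <- function(U, d, fluid = water_properties(37), transition = 2100) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(d <= 0)) stop("diameter must be positive", call. = FALSE)
  re <- fluid$rho * U * d / fluid$mu
  list(reynolds = re, laminar = re <= transition)
}

#' Pipe-flow shear grid masked to the rocker's achievable range
#'
#' Evaluates the laminar wall shear stress over a grid of bulk velocities and
#' pipe diameters, masking cells where the flow would be turbulent
#' (`Re > 2100`) or where the shear lies outside the range the rocker can
#' actually generate, taken from a measured [speed_sweep()] shear map. This
#' is the equivalence chart between rocker settings and real-world pipe
#' scenarios.
#'
#' @param fluid A [fluid_properties()] object.
#' @param velocities Bulk velocities in m/s.
#' @param diameters Pipe diameters in metres.
#' @param map A `shear_map` giving the achievable shear range.
#' @param mask_basis Achievable range from the `"peak"` (default, most
#'   permissive) or `"avg"` map.
#' @param transition Transition Reynolds number.
#' @return An object of class `equivalence_grid`: list with `velocities`,
#'   `diameters`, matrix `tau` (velocity by diameter, N/m^2), logical matrix
#'   `masked`, and the achievable `tau_range`.
#' @export
equivalence_grid <- function(fluid = water_properties(37),
                             velocities = seq(0.01, 0.6, length.out = 60),
                             diameters = seq(1e-3, 3e-2, length.out = 60),
                             map, mask_basis = c("peak", "avg"),
                             transition = 2100) {
  mask_basis <- match.arg(mask_basis)
  stopifnot(inherits(map, "shear_map"))
  m <- map[[mask_basis]][!map$failed, , drop = FALSE]
  if (length(m) == 0 || all(is.na(m)))
    stop("shear map contains no successful rows", call. = FALSE)
  tau_range <- range(m, na.rm = TRUE)
  tau <- outer(velocities, diameters,
               function(U, d) 4 * fluid$mu * U / (d / 2))
  re <- outer(velocities, diameters, function(U, d) fluid$rho * U * d /
                fluid$mu)
  masked <- re > transition | tau < tau_range[1] | tau > tau_range[2]
  structure(list(velocities = velocities, diameters = diameters,
                 tau = tau, masked = masked, tau_range = tau_range,
                 mask_basis = mask_basis, fluid = fluid),
            class = "equivalence_grid")
}

#' Convert catheter French size to diameter
#'
#' One French (Fr) is one third of a millimetre of diameter.
#'
#' @param fr Size in French units.
#' @return Diameter in metres.
#' @export
french_to_diameter <- function(fr) fr / 3 * 1e-3

#' Convert needle/catheter gauge to inner diameter
#'
#' Fixed lookup of nominal inner diameters for common hypodermic/catheter
#' gauges (ISO 9626 nominal values).
#'
#' @param gauge Integer gauge size (supported: 14, 16, 18, 20, 22, 24, 26).
#' @return Inner diameter in metres.
#' @export
gauge_to_diameter <- function(gauge) {
  tbl <- c(`14` = 1.60e-3, `16` = 1.19e-3, `18` = 0.84e-3, `20` = 0.60e-3,
           `22` = 0.41e-3, `24` = 0.31e-3, `26` = 0.26e-3)
  key <- as.character(gauge)
  if (any(!key %in% names(tbl)))
    stop("unsupported gauge size; supported: 14,16,18,20,22,24,26",
         call. = FALSE)
  unname(tbl[key])
}

#' Built-in real-world pipe scenarios where biofilm growth is problematic
#'
#' Four preconfigured scenarios matching the equivalence-chart regions:
#' \describe{
#'   \item{I}{Urethral catheters, 12 and 18 Fr; velocities 8--35 and
#'     15--60 cm/s over low to high bladder pressure (literature values, not
#'     recomputed from a pressure model).}
#'   \item{II}{Venous infusion catheters, 16 and 24 G; velocities from
#'     1.7/4.2 cm/s at 10 cm infusion-set height to over 130/200 cm/s at
#'     100 cm.}
#'   \item{III}{Hemodialysis: 5 mm bloodlines and 9 mm pump tubing at
#'     200--400 mL/min.}
#'   \item{IV}{Household drinking-water pipes, 1.0--2.5 cm diameter at about
#'     1 L/min peak draw (see `flow_interpretation`).}
#' }
#'
#' @param region_iv_flow Flow-rate interpretation for region IV:
#'   `"L_per_min"` (default; reproduces household draw velocities of
#'   3.4--21 cm/s) or `"L_per_s"` (mains-scale flows, mostly turbulent).
#' @return A list of `pipe_scenario` objects with fields `label`,
#'   `description`, `diameters` (m), and either `flow_rates` (m^3/s) or
#'   `velocities` (m/s).
#' @export
builtin_scenarios <- function(region_iv_flow = c("L_per_min", "L_per_s")) {
  region_iv_flow <- match.arg(region_iv_flow)
  q_iv <- if (region_iv_flow == "L_per_min") 1e-3 / 60 else 1e-3
  sc <- list(
    structure(list(
      label = "I", description = "urethral catheters (12 and 18 Fr)",
      diameters = french_to_diameter(c(12, 18)),
      velocities = c(0.08, 0.60),
      velocity_note = "literature range over 5-20 cmH2O bladder pressure"),
      class = "pipe_scenario"),
    structure(list(
      label = "II", description = "venous infusion catheters (16 and 24 G)",
      diameters = gauge_to_diameter(c(16, 24)),
      velocities = c(0.017, 2.0),
      velocity_note = "literature range over 10-100 cm infusion height"),
      class = "pipe_scenario"),
    structure(list(
      label = "III",
      description = "hemodialysis bloodlines (5 mm) and pump tubing (9 mm)",
      diameters = c(5e-3, 9e-3),
      flow_rates = c(200e-6, 400e-6) / 60),
      class = "pipe_scenario"),
    structure(list(
      label = "IV",
      description = "household drinking-water pipes (1.0-2.5 cm)",
      diameters = c(1.0e-2, 2.5e-2),
      flow_rates = c(q_iv, q_iv)),
      class = "pipe_scenario"))
  names(sc) <- vapply(sc, `[[`, "", "label")
  sc
}

#' @export
print.pipe_scenario <- function(x, ...) {
  cat(sprintf("pipe_scenario %s: %s\n", x$label, x$description))
  invisible(x)
}

#' Bulk velocity range spanned by a pipe scenario
#'
#' For scenarios specified by flow rate, evaluates `Q / (pi R^2)` over the
#' corners of the diameter/flow ranges; for velocity-specified scenarios
#' returns the stored range.
#'
#' @param scenario A `pipe_scenario` from [builtin_scenarios()].
#' @return Numeric range `c(min, max)` in m/s.
#' @export
scenario_velocity_range <- function(scenario) {
  stopifnot(inherits(scenario, "pipe_scenario"))
  if (!is.null(scenario$velocities)) return(range(scenario$velocities))
  u <- outer(scenario$flow_rates, scenario$diameters / 2,
             function(Q, R) bulk_velocity(Q, R))
  range(u)
}
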