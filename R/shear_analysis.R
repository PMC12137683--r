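#' Period-averaged wall shear stress per position
#'
#' Averages the magnitude of the wall shear stress over exactly one rocking
#' period at each channel position, the quantity plotted as one row of the
#' speed/position shear map. Magnitudes are used because signed shear cancels
#' by symmetry over a full period.
#'
#' @param rec A `shear_record` from [simulate_rocking_flow()] (or a
#'   compatible synthetic record).
#' @param profile The [make_motion_profile()] used for the run; defaults to
#'   the one stored in the record.
#' @return Numeric vector of mean `|tau|` (N/m^2), one entry per position.
#' @export
period_average <- function(rec, profile = rec$profile) {
  stopifnot(!is.null(rec$tau), !is.null(rec$t))
  period <- profile$period
  span <- max(rec$t) - min(rec$t)
  dt <- if (length(rec$t) > 1) stats::median(diff(rec$t)) else Inf
  if (span < period - dt / 2)
    stop(sprintf("record spans %.4f s, shorter than one period (%.4f s)",
                 span, period), call. = FALSE)
  keep <- rec$t < min(rec$t) + period - dt / 2  # exclude duplicated endpoint
  colMeans(abs(rec$tau[keep, , drop = FALSE]))
}

#' Peak shear stress and threshold-exceedance duration per position
#'
#' For each position, the maximum `|tau|` over the recorded period and the
#' longest contiguous time `|tau|` stays above a threshold, measured on the
#' record's sampling grid. High-shear peaks lasting on the order of 100 ms
#' matter biologically because they outlast the shock absorption of bacterial
#' pili.
#'
#' @param rec A `shear_record`.
#' @param threshold Shear threshold in N/m^2 (non-negative).
#' @return A list with numeric vectors `peak` (N/m^2) and `duration` (s),
#'   one entry per position.
#' @export
peak_and_exceedance <- function(rec, threshold = 1) {
  stopifnot(!is.null(rec$tau))
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  at <- abs(rec$tau)
  dt <- if (length(rec$t) > 1) stats::median(diff(rec$t)) else 0
  peak <- apply(at, 2, max)
  duration <- apply(at, 2, function(col) {
    above <- col > threshold
    if (!any(above)) return(0)
    r <- rle(above)
    max(r$lengths[r$values]) * dt
  })
  list(peak = peak, duration = duration)
}

#' Sweep rocking speeds into a shear map
#'
#' Runs [simulate_rocking_flow()] once per rocking speed and stacks the
#' period-averaged and peak shear per position into a speed-by-position map,
#' the translation table between rocker settings and the shear stress a
#' biofilm experiences. Failed runs are reported and masked with `NA` rows
#' rather than aborting the sweep.
#'
#' @param geom A [well_geometry()].
#' @param fill_volume Fill volume in cubic metres.
#' @param speeds Rocking speeds to sweep, degrees per second (device range
#'   1--99).
#' @param max_angle Maximum rocking angle in degrees.
#' @param fluid A [fluid_properties()] object.
#' @param config A [solver_config()].
#' @param max_accel Maximum angular acceleration (deg/s^2), `Inf` by default.
#' @return An object of class `shear_map`: list with `speeds` (deg/s,
#'   sorted), `x` (m), matrices `avg` and `peak` (speed by position, N/m^2),
#'   `failed` (logical per speed), and metadata.
#' @export
speed_sweep <- function(geom = well_geometry(), fill_volume = 5e-6,
                        speeds = c(10, 20, 30, 40, 50, 70, 100),
                        max_angle = 7,
                        fluid = water_properties(37),
                        config = solver_config(),
                        max_accel = Inf) {
  speeds <- sort(unique(speeds))
  # the device caps at 99 deg/s; clamp a conventional 100 to the cap
  speeds_run <- pmin(speeds, 99)
  n <- config$n_cells
  avg <- peak <- matrix(NA_real_, nrow = length(speeds), ncol = n)
  failed <- logical(length(speeds))
  x <- NULL
  for (i in seq_along(speeds)) {
    res <- tryCatch({
      prof <- make_motion_profile(
        motion_settings(max_angle, speeds_run[i], max_accel))
      rec <- simulate_rocking_flow(geom, fill_volume, prof, fluid, config)
      pe <- peak_and_exceedance(rec, threshold = 0)
      list(x = rec$x, avg = period_average(rec), peak = pe$peak)
    }, error = function(e) {
      warning(sprintf("speed %g deg/s failed: %s", speeds[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) { failed[i] <- TRUE; next }
    x <- res$x
    avg[i, ] <- res$avg
    peak[i, ] <- res$peak
  }
  structure(list(speeds = speeds, x = x, avg = avg, peak = peak,
                 failed = failed, fill_volume = fill_volume,
                 max_angle = max_angle, fluid = fluid, config = config),
            class = "shear_map")
}

#' @export
print.shear_map <- function(x, ...) {
  ok <- !x$failed
  cat(sprintf(
    paste0("shear_map: %d speeds (%g-%g deg/s) x %d positions, ",
           "fill %.1f mL at +/-%g deg\n  max avg |tau| %.3g, ",
           "max peak |tau| %.3g N/m^2\n"),
    length(x$speeds), min(x$speeds), max(x$speeds), ncol(x$avg),
    x$fill_volume * 1e6, x$max_angle,
    max(x$avg[ok, ], na.rm = TRUE), max(x$peak[ok, ], na.rm = TRUE)))
  invisible(x)
}

#' Locate the resonant rocking speed in a shear map
#'
#' The resonant speed is the sweep row attaining the global peak shear
#' stress; ties break toward the lower speed. If the peak sits on an endpoint
#' of the sweep the map is monotone over the sampled range and no interior
#' resonance can be claimed, which is flagged.
#'
#' @param map A `shear_map` from [speed_sweep()].
#' @param basis Use the `"peak"` (default) or `"avg"` matrix.
#' @return A list with `speed` (deg/s), `value` (N/m^2) and logical
#'   `interior` (`FALSE` when the maximum lies on a sweep endpoint).
#' @export
find_resonant_speed <- function(map, basis = c("peak", "avg")) {
  basis <- match.arg(basis)
  stopifnot(inherits(map, "shear_map"))
  m <- map[[basis]]
  ok <- !map$failed
  if (sum(ok) < 3)
    stop("need at least 3 successful sweep rows", call. = FALSE)
  row_max <- apply(m, 1, function(r) if (all(is.na(r))) -Inf else max(r,
                                                                 na.rm = TRUE))
  i <- which(row_max == max(row_max))[1]   # ties toward the lower speed
  interior <- i > min(which(ok)) && i < max(which(ok))
  list(speed = map$speeds[i], value = row_max[i], interior = interior)
}

#' Shallow-water estimate of the resonant rocking speed
#'
#' A gravity wave on mean depth `h` travels at `sqrt(g h)`; equating that to
#' the resonance condition (the front traverses the channel in one
#' half-period) gives the rocking speed
#' `omega* = 2 alpha sqrt(g h) / L` (degrees per second when `alpha` is in
#' degrees). For a 5 mL fill of the default well this lands near 27 deg/s,
#' inside the 25--50 deg/s window where the measured shear maps peak.
#'
#' @param geom A [well_geometry()].
#' @param fill_volume Fill volume in cubic metres.
#' @param fluid A [fluid_properties()] object (for gravity).
#' @param max_angle Maximum rocking angle in degrees.
#' @return Estimated resonant rocking speed in degrees per second.
#' @examples
#' resonant_speed_estimate(well_geometry(), 5e-6)
#' @export
resonant_speed_estimate <- function(geom = well_geometry(),
                                    fill_volume = 5e-6,
                                    fluid = water_properties(37),
                                    max_angle = 7) {
  h <- fill_depth(fill_volume, geom)
  2 * max_angle * sqrt(fluid$gravity * h) / geom$length
}

#' Convert wall shear stress to force on a single attached cell
#'
#' Multiplies the wall shear stress by the effective surface area over which
#' a surface-attached bacterium intercepts the flow. The default area of
#' 33.3 square micrometres reproduces the conventional conversions of about
#' 15 pN at 0.46 N/m^2 and 80 pN at 2.4 N/m^2; it is an effective
#' (hydrodynamic) area, larger than the cell's geometric footprint.
#'
#' @param tau Wall shear stress in N/m^2.
#' @param effective_area Effective cell area in m^2 (default 33.3e-12).
#' @return Force in newtons.
#' @examples
#' force_on_cell(2.4) * 1e12 # about 80 pN
#' @export
force_on_cell <- function(tau, effective_area = 33.3e-12) {
  if (!is.numeric(effective_area) || effective_area <= 0)
    stop("effective_area must be positive", call. = FALSE)
  tau * effective_area
}
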