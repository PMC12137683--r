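#' Rectangular culture-plate well geometry
#'
#' Describes one rectangular well of a rocking-platform culture plate as a
#' flat-bottomed channel. The default dimensions correspond to a four-well
#' plate whose 8 cm long channels are sized to hold a 26 x 76 mm microscope
#' slide and 24 mL of liquid. The tilt pivot sits at the channel mid-point
#' ("CoC", centre of channel), which is also the origin of the x axis.
#'
#' @param length Channel length L in metres (default 0.08).
#' @param width Channel width W in metres (default 0.026).
#' @param capacity Well capacity in cubic metres (default 24e-6, i.e. 24 mL).
#' @param pivot_x Position of the rocking axis along the channel, metres from
#'   the channel centre (default 0).
#' @param max_depth Maximum usable well depth in metres (default 0.0145, the
#'   plate height). The capacity must fit below this depth.
#' @return An object of class `well_geometry`.
#' @examples
#' geom <- well_geometry()
#' fill_depth(5e-6, geom) # 5 mL -> 2.4 mm
#' @export
well_geometry <- function(length = 0.08, width = 0.026, capacity = 24e-6,
                          pivot_x = 0, max_depth = 0.0145) {
  stopifnot(is.numeric(length), is.numeric(width), is.numeric(capacity))
  if (length <= 0 || width <= 0 || capacity <= 0)
    stop("well dimensions and capacity must be positive", call. = FALSE)
  g <- structure(
    list(length = length, width = width, capacity = capacity,
         pivot_x = pivot_x, max_depth = max_depth),
    class = "well_geometry")
  if (fill_depth(capacity, g) > max_depth + 1e-12)
    stop("well capacity does not fit below max_depth for these dimensions",
         call. = FALSE)
  g
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(
    "well_geometry: L = %.1f mm, W = %.1f mm, capacity = %.1f mL (depth %.2f mm at capacity)\n",
    x$length * 1e3, x$width * 1e3, x$capacity * 1e6,
    fill_depth(x$capacity, x) * 1e3))
  invisible(x)
}

#' Convert fill volume to liquid depth
#'
#' For a flat-bottomed rectangular well the level liquid depth is
#' `volume / (L * W)`. Inverse of [volume_at_depth()].
#'
#' @param volume Fill volume in cubic metres.
#' @param geom A [well_geometry()].
#' @return Depth in metres.
#' @export
fill_depth <- function(volume, geom = well_geometry()) {
  stopifnot(inherits(geom, "well_geometry"))
  if (any(volume < 0))
    stop("fill volume must be non-negative", call. = FALSE)
  if (any(volume > geom$capacity + 1e-15))
    stop(sprintf("fill volume %.3g m^3 exceeds well capacity %.3g m^3",
                 max(volume), geom$capacity), call. = FALSE)
  volume / (geom$length * geom$width)
}

#' Convert liquid depth to fill volume
#'
#' @param depth Level liquid depth in metres.
#' @inheritParams fill_depth
#' @return Volume in cubic metres.
#' @export
volume_at_depth <- function(depth, geom = well_geometry()) {
  stopifnot(inherits(geom, "well_geometry"))
  if (any(depth < 0)) stop("depth must be non-negative", call. = FALSE)
  geom$length * geom$width * depth
}
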