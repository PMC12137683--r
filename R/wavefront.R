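#' Wavefront position trace
#'
#' A time series of the position of an advancing wet/dry front, relative to
#' the centre of the channel (CoC). Traces are produced by [detect_front()]
#' from simulated depth fields or by [gen_wavefront_trace()] synthetically.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param position Front positions in metres relative to CoC.
#' @param direction `"left-to-right"` or `"right-to-left"`.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `wavefront_trace`.
#' @export
wavefront_trace <- function(t, position,
                            direction = c("left-to-right", "right-to-left"),
                            meta = list()) {
  direction <- match.arg(direction)
  if (length(t) != length(position))
    stop("t and position lengths differ", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  structure(list(t = as.numeric(t), position = as.numeric(position),
                 direction = direction, meta = meta),
            class = "wavefront_trace")
}

#' @export
print.wavefront_trace <- function(x, ...) {
  cat(sprintf("wavefront_trace: %d samples, %s, x in [%.1f, %.1f] cm\n",
              length(x$t), x$direction,
              100 * min(x$position), 100 * max(x$position)))
  invisible(x)
}

#' Detect advancing wavefronts in a depth-field record
#'
#' Tracks the outermost wet/dry interface of the sloshing fluid in each
#' snapshot (position linearly interpolated to the threshold crossing between
#' cells), splits the interface trajectory into monotone traversals, and
#' keeps those that pass through the centre of the channel -- the measurement
#' point used for wavefront velocimetry. Rightward-moving fronts come from
#' the right edge of the wet region, leftward-moving fronts from the left
#' edge. Snapshots where the fluid touches the wall on that side yield no
#' front.
#'
#' @param rec A record with uniform sample times `t`, positions `x` and a
#'   depth matrix `h` (time by position), e.g. a `shear_record`.
#' @param depth_threshold Depth defining "wet", metres. Defaults to 10 times
#'   the solver dry threshold so a residual numerical film is not counted.
#' @param min_points Minimum samples for a traversal to be kept.
#' @return A list of [wavefront_trace()] objects (possibly empty).
#' @export
detect_front <- function(rec, depth_threshold = NULL, min_points = 3) {
  stopifnot(!is.null(rec$h), !is.null(rec$t), !is.null(rec$x))
  if (is.null(depth_threshold)) {
    thr0 <- if (!is.null(rec$config$dry_threshold))
      rec$config$dry_threshold else 1e-6
    depth_threshold <- 10 * thr0
  }
  h <- rec$h; x <- rec$x; tt <- rec$t
  n <- length(x)
  dx <- x[2] - x[1]
  edge_pos <- function(hrow, side) {
    wet <- hrow > depth_threshold
    if (!any(wet) || all(wet)) return(NA_real_)
    if (side == "right") {
      i <- max(which(wet))
      if (i == n) return(NA_real_)            # fluid at the wall
      frac <- (hrow[i] - depth_threshold) / (hrow[i] - hrow[i + 1])
      x[i] + frac * dx
    } else {
      i <- min(which(wet))
      if (i == 1) return(NA_real_)
      frac <- (hrow[i] - depth_threshold) / (hrow[i] - hrow[i - 1])
      x[i] - frac * dx
    }
  }
  xR <- apply(h, 1, edge_pos, side = "right")
  xL <- apply(h, 1, edge_pos, side = "left")

  traces <- list()
  harvest <- function(series, increasing, direction) {
    ok <- !is.na(series)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      if (length(idx) < 2) next
      d <- diff(series[idx])
      mono <- if (increasing) d > 0 else d < 0
      # split the run into maximal monotone segments
      seg_id <- cumsum(c(TRUE, diff(mono) != 0))
      for (s in unique(seg_id)) {
        pick <- which(seg_id == s)
        if (!mono[pick[1]]) next
        sub <- idx[c(pick, pick[length(pick)] + 1)]
        if (length(sub) < min_points) next
        p <- series[sub]
        if (min(p) < 0 && max(p) > 0)         # must pass through CoC
          traces[[length(traces) + 1]] <<- wavefront_trace(
            tt[sub], p, direction,
            meta = list(depth_threshold = depth_threshold))
      }
    }
  }
  harvest(xR, increasing = TRUE, direction = "left-to-right")
  harvest(xL, increasing = FALSE, direction = "right-to-left")
  traces
}

#' Wavefront velocity at the centre of the channel
#'
#' Ordinary least-squares slope of front position versus time, restricted to
#' positions within `window_halfwidth` of the channel centre (default
#' +/- 2 cm), with the standard error of the slope.
#'
#' @param trace A [wavefront_trace()].
#' @param window_halfwidth Half-width of the fit window around CoC, metres.
#' @return A list with `velocity` (m/s), `se` (m/s) and `n_points`.
#' @examples
#' tr <- wavefront_trace(seq(0, 1, 0.02), seq(0, 1, 0.02) * 0.15 - 0.075)
#' coc_velocity(tr)$velocity # 0.15
#' @export
coc_velocity <- function(trace, window_halfwidth = 0.02) {
  stopifnot(inherits(trace, "wavefront_trace"))
  keep <- abs(trace$position) <= window_halfwidth
  if (sum(keep) < 3)
    stop(sprintf("only %d samples within +/-%g m of CoC; need at least 3",
                 sum(keep), window_halfwidth), call. = FALSE)
  tt <- trace$t[keep]
  pp <- trace$position[keep]
  fit <- stats::lm(pp ~ tt)
  slope <- unname(stats::coef(fit)[2])
  # slope standard error computed directly (avoids the zero-residual
  # warning summary.lm emits for noiseless synthetic traces)
  n <- length(tt)
  sxx <- sum((tt - mean(tt))^2)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  list(velocity = slope, se = sqrt(s2 / sxx), n_points = n)
}

#' Box-plot statistics with 1.5 IQR outlier rule
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7).
#' Outliers lie more than `1.5 * IQR` beyond the quartiles; whiskers span the
#' minimum and maximum of the non-outlying values.
#'
#' @param values Numeric vector (at least one finite value).
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers` and `n`.
#' @export
box_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inl <- values[values >= lo & values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inl), whisker_high = max(inl),
       outliers = out, n = length(values))
}
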