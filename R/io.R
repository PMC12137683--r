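# write a data frame as CSV with numeric columns at full double precision,
# so our own readers round-trip values bit-identically
write_csv_exact <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a shear record to CSV (long format)
#'
#' Writes one row per (time, position) sample with columns `x_m`, `t_s`,
#' `tau_Pa`, `theta_rad`. Readable back with [read_shear_record_csv()].
#'
#' @param rec A `shear_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shear_record_csv <- function(rec, path) {
  stopifnot(inherits(rec, "shear_record"))
  df <- data.frame(
    x_m = rep(rec$x, each = length(rec$t)),
    t_s = rep(rec$t, times = length(rec$x)),
    tau_Pa = as.vector(rec$tau),
    theta_rad = rep(rec$theta, times = length(rec$x)))
  write_csv_exact(df, path)
}

#' Read a long-format shear record CSV
#'
#' @param path CSV written by [write_shear_record_csv()].
#' @return A data frame with columns `x_m`, `t_s`, `tau_Pa`, `theta_rad`.
#' @export
read_shear_record_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("x_m", "t_s", "tau_Pa", "theta_rad")
  if (!all(need %in% names(df)))
    stop("not a shear-record CSV (missing columns)", call. = FALSE)
  df
}

#' Compact JSON summary of a shear record
#'
#' Per-position mean and peak `|tau|` plus run metadata, written as JSON.
#'
#' @param rec A `shear_record`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_shear_record_summary <- function(rec, path) {
  stopifnot(inherits(rec, "shear_record"))
  pe <- peak_and_exceedance(rec, threshold = 0)
  obj <- list(
    x_m = rec$x,
    mean_abs_tau_Pa = unname(period_average(rec)),
    peak_abs_tau_Pa = unname(pe$peak),
    fill_volume_m3 = rec$fill_volume,
    max_angle_deg = rec$profile$settings$max_angle,
    max_speed_deg_s = rec$profile$settings$max_speed,
    volume_drift = rec$diagnostics$volume_drift)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a shear map to CSV matrices
#'
#' Writes two CSV files, `<stem>_avg.csv` and `<stem>_peak.csv`, each with a
#' first column `speed_deg_s` and one column per channel position, plus a
#' JSON sidecar `<stem>_meta.json` with the run metadata and configuration
#' hash.
#'
#' @param map A `shear_map` from [speed_sweep()].
#' @param stem Output path stem (without extension).
#' @return The three paths, invisibly.
#' @export
write_shear_map <- function(map, stem) {
  stopifnot(inherits(map, "shear_map"))
  cols <- sprintf("x_%04.1f_mm", map$x * 1e3)
  for (what in c("avg", "peak")) {
    df <- data.frame(speed_deg_s = map$speeds, map[[what]])
    names(df) <- c("speed_deg_s", cols)
    write_csv_exact(df, paste0(stem, "_", what, ".csv"))
  }
  meta <- list(fill_volume_m3 = map$fill_volume,
               max_angle_deg = map$max_angle,
               fluid = unclass(map$fluid),
               solver = unclass(map$config),
               config_hash = config_hash(list(
                 fill = map$fill_volume, angle = map$max_angle,
                 fluid = unclass(map$fluid), solver = unclass(map$config))))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(stem, "_avg.csv"), paste0(stem, "_peak.csv"),
              paste0(stem, "_meta.json")))
}

#' Export a wavefront trace to CSV
#'
#' Two columns, `t_s` and `x_m`.
#'
#' @param trace A [wavefront_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wavefront_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "wavefront_trace"))
  write_csv_exact(data.frame(t_s = trace$t, x_m = trace$position), path)
}

#' Read a wavefront trace CSV
#'
#' @param path CSV with columns `t_s`, `x_m`.
#' @param direction Direction label for the trace.
#' @return A [wavefront_trace()].
#' @export
read_wavefront_trace_csv <- function(path,
                                     direction = "left-to-right") {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "x_m") %in% names(df)))
    stop("not a wavefront-trace CSV (missing columns)", call. = FALSE)
  wavefront_trace(df$t_s, df$x_m, direction)
}

#' Export a thermal trace to CSV
#'
#' Columns `t_s`, `T_plate_C`, `T_water_C`, `duty`.
#'
#' @param trace A `thermal_trace` from [simulate_step_response()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermal_trace_csv <- function(trace, path) {
  write_csv_exact(as.data.frame(trace)[, c("t_s", "T_plate_C",
                                           "T_water_C", "duty")], path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `geometry`, `motion`,
#' `fluid`, `solver`, `analysis`, `thermal` and `output`, rejects unknown
#' sections or keys, fills defaults, and attaches a content hash so outputs
#' can be traced back to the exact configuration.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @param overrides Named list of `section$key` overrides applied after
#'   reading, e.g. `list(motion = list(max_speed_deg_s = 30))`.
#' @return An object of class `run_config`: validated list with the
#'   constructed `geometry`, `motion` settings, `fluid`, `solver` objects
#'   and `config_hash`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  known <- list(
    geometry = c("length_m", "width_m", "capacity_m3", "pivot_x_m",
                 "max_depth_m"),
    motion = c("max_angle_deg", "max_speed_deg_s", "max_accel_deg_s2"),
    fluid = c("temperature_C", "rho", "mu", "gravity"),
    solver = c("n_cells", "cfl_number", "dry_threshold_m", "spinup_periods",
               "record_periods", "record_rate_hz", "include_euler_forcing"),
    analysis = c("fill_volume_mL", "speeds_deg_s", "exceedance_threshold_Pa",
                 "effective_cell_area_m2"),
    thermal = c("setpoint_C", "duration_s", "kp", "ki", "kd",
                "sample_interval_s"),
    output = c("directory", "stem"))
  raw <- if (is.null(path)) list() else {
    if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  for (section in names(overrides)) {
    raw[[section]] <- utils::modifyList(
      if (is.null(raw[[section]])) list() else raw[[section]],
      overrides[[section]])
  }
  bad_sections <- setdiff(names(raw), names(known))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  for (section in names(raw)) {
    bad <- setdiff(names(raw[[section]]), known[[section]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  gv <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  geom <- well_geometry(
    length = gv("geometry", "length_m", 0.08),
    width = gv("geometry", "width_m", 0.026),
    capacity = gv("geometry", "capacity_m3", 24e-6),
    pivot_x = gv("geometry", "pivot_x_m", 0),
    max_depth = gv("geometry", "max_depth_m", 0.0145))
  motion <- motion_settings(
    max_angle = gv("motion", "max_angle_deg", 7),
    max_speed = gv("motion", "max_speed_deg_s", 40),
    max_accel = gv("motion", "max_accel_deg_s2", Inf))
  fluid <- if (!is.null(raw$fluid$rho) && !is.null(raw$fluid$mu)) {
    fluid_properties(raw$fluid$rho, raw$fluid$mu,
                     gv("fluid", "temperature_C", NA_real_),
                     gv("fluid", "gravity", 9.81))
  } else {
    water_properties(gv("fluid", "temperature_C", 37),
                     gv("fluid", "gravity", 9.81))
  }
  solver <- solver_config(
    n_cells = gv("solver", "n_cells", 400),
    cfl = gv("solver", "cfl_number", 0.4),
    dry_threshold = gv("solver", "dry_threshold_m", 1e-6),
    spinup_periods = gv("solver", "spinup_periods", 5),
    record_periods = gv("solver", "record_periods", 1),
    record_rate = gv("solver", "record_rate_hz", 1000),
    include_euler_forcing = gv("solver", "include_euler_forcing", FALSE))
  cfg <- list(
    geometry = geom, motion = motion, fluid = fluid, solver = solver,
    analysis = list(
      fill_volume = gv("analysis", "fill_volume_mL", 5) * 1e-6,
      speeds = gv("analysis", "speeds_deg_s", c(10, 20, 30, 40, 50, 70, 100)),
      exceedance_threshold = gv("analysis", "exceedance_threshold_Pa", 1),
      effective_cell_area = gv("analysis", "effective_cell_area_m2",
                               33.3e-12)),
    thermal = list(
      setpoint = gv("thermal", "setpoint_C", 37),
      duration = gv("thermal", "duration_s", 1800),
      gains = pid_gains(kp = gv("thermal", "kp", 0.3),
                        ki = gv("thermal", "ki", 0.004),
                        kd = gv("thermal", "kd", 0),
                        sample_interval = gv("thermal", "sample_interval_s",
                                             0.5))),
    output = list(directory = gv("output", "directory", "."),
                  stem = gv("output", "stem", "rockersim")))
  cfg$config_hash <- config_hash(raw)
  structure(cfg, class = "run_config")
}

#' Deterministic content hash of a configuration
#'
#' FNV-1a 32-bit hash of the canonical JSON serialisation; stable across
#' sessions, used to stamp outputs with the configuration that produced
#' them.
#'
#' @param x Any JSON-serialisable R object.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes %% 256) {
    # xor touches only the low byte since b < 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
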