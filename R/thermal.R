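#' Lumped two-node thermal plant of the incubation platform
#'
#' Models the thermal path from the Peltier element through the aluminium
#' sample holder ("plate") into the water in the wells as two lumped thermal
#' nodes with linear conductances, plus leakage from both nodes to ambient.
#' The actuator injects (or extracts) heat at the plate node, limited by the
#' heating and cooling power of the Peltier stage; cooling is weaker than
#' heating, which bounds the reachable floor temperature (the hardware
#' reaches about 35 degC below ambient).
#'
#' Default capacities correspond to roughly 28 mL of water (four wells at
#' 7 mL) and a ~200 g aluminium holder; conductances are chosen so step
#' responses settle in minutes, matching the qualitative behaviour of the
#' hardware.
#'
#' @param C_plate,C_water Heat capacities of the plate and water nodes (J/K).
#' @param k_peltier_plate Conductance used to express actuator coupling; the
#'   actuator power is injected directly at the plate node, so this is kept
#'   for completeness and not used by the integrator.
#' @param k_plate_water Plate-to-water conductance (W/K).
#' @param k_plate_ambient,k_water_ambient Leakage conductances to ambient
#'   (W/K).
#' @param ambient Ambient temperature (degC).
#' @param max_heating,max_cooling Actuator power limits (W, both positive).
#' @param T_plate0,T_water0 Initial node temperatures (degC); default
#'   ambient.
#' @return An object of class `thermal_plant`.
#' @export
thermal_plant <- function(C_plate = 180, C_water = 117,
                          k_peltier_plate = 5,
                          k_plate_water = 2.0,
                          k_plate_ambient = 0.5, k_water_ambient = 0.2,
                          ambient = 21,
                          max_heating = 40, max_cooling = 20,
                          T_plate0 = ambient, T_water0 = ambient) {
  if (C_plate <= 0 || C_water <= 0)
    stop("heat capacities must be positive", call. = FALSE)
  if (k_plate_water < 0 || k_plate_ambient < 0 || k_water_ambient < 0)
    stop("conductances must be non-negative", call. = FALSE)
  if (max_heating <= 0 || max_cooling <= 0)
    stop("actuator power limits must be positive", call. = FALSE)
  structure(list(C_plate = C_plate, C_water = C_water,
                 k_peltier_plate = k_peltier_plate,
                 k_plate_water = k_plate_water,
                 k_plate_ambient = k_plate_ambient,
                 k_water_ambient = k_water_ambient,
                 ambient = ambient,
                 max_heating = max_heating, max_cooling = max_cooling,
                 T_plate0 = T_plate0, T_water0 = T_water0),
            class = "thermal_plant")
}

#' Discrete PID controller gains
#'
#' @param kp,ki,kd Proportional (per K), integral (per K per s) and
#'   derivative (per K s) gains.
#' @param output_limit Symmetric duty-cycle saturation (default 1).
#' @param sample_interval Controller sample interval in seconds.
#' @param integral_clamp Anti-windup clamp on `ki * integral`; defaults to
#'   the output limit.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 0.3, ki = 0.004, kd = 0,
                      output_limit = 1, sample_interval = 0.5,
                      integral_clamp = output_limit) {
  if (sample_interval <= 0) stop("sample_interval must be positive",
                                 call. = FALSE)
  if (output_limit <= 0) stop("output_limit must be positive", call. = FALSE)
  structure(list(kp = kp, ki = ki, kd = kd, output_limit = output_limit,
                 sample_interval = sample_interval,
                 integral_clamp = integral_clamp),
            class = "pid_gains")
}

#' One update of the discrete PID controller
#'
#' Standard positional PID with clamped integral (anti-windup) and output
#' saturation. Positive duty means heating, negative cooling; the magnitude
#' is the PWM duty cycle, whose mean power drives the Peltier stage (the
#' 490 Hz switching itself is far faster than any thermal time constant and
#' is not resolved).
#'
#' @param gains A [pid_gains()].
#' @param setpoint,measured Setpoint and measured temperature (degC).
#' @param state Controller state from the previous call, or `NULL` to
#'   initialise (zero integral, no previous error).
#' @return A list with `duty` in `[-limit, limit]` and the updated `state`.
#' @export
pid_step <- function(gains, setpoint, measured, state = NULL) {
  stopifnot(inherits(gains, "pid_gains"))
  if (is.null(state)) state <- list(integral = 0, prev_error = NA_real_)
  dt <- gains$sample_interval
  e <- setpoint - measured
  integral <- state$integral + e * dt
  if (gains$ki > 0) {
    cl <- gains$integral_clamp / gains$ki
    integral <- max(-cl, min(cl, integral))
  }
  deriv <- if (is.na(state$prev_error)) 0 else (e - state$prev_error) / dt
  u <- gains$kp * e + gains$ki * integral + gains$kd * deriv
  duty <- max(-gains$output_limit, min(gains$output_limit, u))
  list(duty = duty, state = list(integral = integral, prev_error = e))
}

#' NTC thermistor model and ADC conversion
#'
#' Beta-equation model of an NTC thermistor read through a resistive divider
#' into an ADC. The thermistor sits on the low side of the divider, so the
#' ADC reading is `full_scale * R_t / (R_t + R_divider)`.
#'
#' @param R0 Thermistor resistance at `T0`, ohms (default 10 kOhm).
#' @param T0 Reference temperature in kelvin (default 298.15).
#' @param beta Beta coefficient in kelvin (default 3950).
#' @param R_divider Fixed divider resistance, ohms (default 10 kOhm).
#' @param adc_full_scale Full-scale ADC counts (default 1023, 10-bit).
#' @return An object of class `thermistor_model`.
#' @export
thermistor_model <- function(R0 = 10e3, T0 = 298.15, beta = 3950,
                             R_divider = 10e3, adc_full_scale = 1023) {
  vals <- c(R0, T0, beta, R_divider, adc_full_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thermistor parameters must be positive", call. = FALSE)
  structure(list(R0 = R0, T0 = T0, beta = beta, R_divider = R_divider,
                 adc_full_scale = adc_full_scale),
            class = "thermistor_model")
}

#' Convert ADC counts to temperature through the thermistor model
#'
#' Inverts the divider to the thermistor resistance and applies the beta
#' equation `T = 1 / (1/T0 + log(R/R0)/beta)`. Readings at either ADC rail
#' indicate an open or shorted sensor and raise an error.
#'
#' @param adc_counts ADC reading(s), strictly between 0 and full scale.
#' @param model A [thermistor_model()].
#' @return Temperature(s) in degrees Celsius.
#' @export
thermistor_to_temperature <- function(adc_counts, model = thermistor_model()) {
  stopifnot(inherits(model, "thermistor_model"))
  if (any(adc_counts <= 0 | adc_counts >= model$adc_full_scale))
    stop("sensor fault: ADC reading at rail (open or shorted thermistor)",
         call. = FALSE)
  R <- model$R_divider * adc_counts / (model$adc_full_scale - adc_counts)
  thermistor_resistance_to_temperature(R, model)
}

#' @rdname thermistor_to_temperature
#' @param R Thermistor resistance in ohms.
#' @export
thermistor_resistance_to_temperature <- function(R, model = thermistor_model()) {
  stopifnot(inherits(model, "thermistor_model"))
  if (any(R <= 0)) stop("resistance must be positive", call. = FALSE)
  1 / (1 / model$T0 + log(R / model$R0) / model$beta) - 273.15
}

#' Simulate a closed-loop temperature step response
#'
#' Forward-integrates the two-node plant ODEs with PID-modulated actuator
#' power (duty times the heating or cooling limit, i.e. the mean of the PWM
#' drive). The controller samples the chosen sensor at its sample interval;
#' between controller updates the plant is integrated with a fixed Euler
#' substep small relative to every thermal time constant.
#'
#' @param plant A [thermal_plant()].
#' @param gains A [pid_gains()].
#' @param setpoint Target temperature (degC).
#' @param duration Simulated time (s).
#' @param sensor Node the controller measures: `"water"` (default, matching
#'   an in-well sensor) or `"plate"`.
#' @param record_interval Output sample spacing (s), default 1.
#' @param duty_trace Optional numeric vector overriding the controller: one
#'   duty value per controller interval (open-loop replay, used for plant
#'   parameter fitting).
#' @return An object of class `thermal_trace`: data frame columns `t_s`,
#'   `T_plate_C`, `T_water_C`, `duty`, with the plant/gains attached as
#'   attributes.
#' @examples
#' tr <- simulate_step_response(thermal_plant(), pid_gains(), 37, 600)
#' tail(tr$T_water_C, 1)
#' @export
simulate_step_response <- function(plant = thermal_plant(),
                                   gains = pid_gains(),
                                   setpoint = 37, duration = 1800,
                                   sensor = c("water", "plate"),
                                   record_interval = 1,
                                   duty_trace = NULL) {
  stopifnot(inherits(plant, "thermal_plant"), inherits(gains, "pid_gains"))
  sensor <- match.arg(sensor)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  dt_ctrl <- gains$sample_interval
  n_ctrl <- ceiling(duration / dt_ctrl)
  # Euler substep: comfortably below the fastest node time constant
  tau_min <- min(plant$C_plate / (plant$k_plate_water +
                                    plant$k_plate_ambient + 1e-12),
                 plant$C_water / (plant$k_plate_water +
                                    plant$k_water_ambient + 1e-12))
  dt_sub <- min(dt_ctrl, tau_min / 20)
  n_sub <- max(1L, ceiling(dt_ctrl / dt_sub))
  dt_sub <- dt_ctrl / n_sub

  Tp <- plant$T_plate0; Tw <- plant$T_water0
  state <- NULL
  n_rec <- floor(duration / record_interval) + 1
  out_t <- numeric(n_rec); out_p <- numeric(n_rec)
  out_w <- numeric(n_rec); out_d <- numeric(n_rec)
  i_rec <- 1L
  out_t[1] <- 0; out_p[1] <- Tp; out_w[1] <- Tw; out_d[1] <- 0
  t <- 0
  for (k in seq_len(n_ctrl)) {
    if (is.null(duty_trace)) {
      meas <- if (sensor == "water") Tw else Tp
      st <- pid_step(gains, setpoint, meas, state)
      duty <- st$duty; state <- st$state
    } else {
      duty <- duty_trace[min(k, length(duty_trace))]
    }
    P <- if (duty >= 0) duty * plant$max_heating else duty * plant$max_cooling
    for (s in seq_len(n_sub)) {
      dTp <- (P - plant$k_plate_water * (Tp - Tw) -
                plant$k_plate_ambient * (Tp - plant$ambient)) / plant$C_plate
      dTw <- (plant$k_plate_water * (Tp - Tw) -
                plant$k_water_ambient * (Tw - plant$ambient)) / plant$C_water
      Tp <- Tp + dt_sub * dTp
      Tw <- Tw + dt_sub * dTw
    }
    if (!is.finite(Tp) || !is.finite(Tw) || abs(Tp) > 1e4)
      stop(sprintf("thermal simulation diverged at t = %.1f s (Tp = %g)",
                   t, Tp), call. = FALSE)
    t <- k * dt_ctrl
    while (i_rec < n_rec && (i_rec) * record_interval <= t + 1e-9) {
      i_rec <- i_rec + 1L
      out_t[i_rec] <- (i_rec - 1) * record_interval
      out_p[i_rec] <- Tp; out_w[i_rec] <- Tw; out_d[i_rec] <- duty
    }
  }
  res <- data.frame(t_s = out_t[1:i_rec], T_plate_C = out_p[1:i_rec],
                    T_water_C = out_w[1:i_rec], duty = out_d[1:i_rec])
  attr(res, "plant") <- plant
  attr(res, "gains") <- gains
  attr(res, "setpoint") <- setpoint
  attr(res, "sensor") <- sensor
  class(res) <- c("thermal_trace", "data.frame")
  res
}

#' Fit plant parameters from a recorded step-response trace
#'
#' Recovers selected two-node plant parameters by least squares: the plant is
#' re-simulated open loop with the recorded duty sequence and candidate
#' parameters, and the squared deviation of both temperature traces is
#' minimised with Nelder-Mead on log-parameters (positivity by
#' construction).
#'
#' @param trace A `thermal_trace` from [simulate_step_response()] (possibly
#'   with added sensor noise) that includes the `duty` column.
#' @param plant A [thermal_plant()] giving the known (fixed) parameters and
#'   starting values for the fitted ones.
#' @param fit Character vector of parameter names to fit (default
#'   `c("C_water", "k_plate_water")`).
#' @param start Optional named numeric starting values for the fitted
#'   parameters (defaults to 1.5x the plant values, deliberately off-truth).
#' @return A list with `estimates` (named), the `optim` convergence code and
#'   the residual sum of squares.
#' @export
fit_plant_parameters <- function(trace, plant,
                                 fit = c("C_water", "k_plate_water"),
                                 start = NULL) {
  stopifnot(inherits(trace, "thermal_trace") || is.data.frame(trace))
  gains <- attr(trace, "gains")
  if (is.null(gains)) gains <- pid_gains()
  duration <- max(trace$t_s)
  rec_int <- stats::median(diff(trace$t_s))
  duty <- trace$duty
  # map the recorded duty (one per record interval) onto controller intervals
  n_ctrl <- ceiling(duration / gains$sample_interval)
  idx <- pmin(length(duty),
              1 + floor((seq_len(n_ctrl) - 0.5) * gains$sample_interval /
                          rec_int))
  duty_ctrl <- duty[idx]
  if (is.null(start)) {
    start <- vapply(fit, function(p) plant[[p]] * 1.5, numeric(1))
    names(start) <- fit
  }
  obj <- function(logpar) {
    p2 <- plant
    for (j in seq_along(fit)) p2[[fit[j]]] <- exp(logpar[j])
    class(p2) <- "thermal_plant"
    sim <- simulate_step_response(p2, gains, setpoint = 0,
                                  duration = duration,
                                  record_interval = rec_int,
                                  duty_trace = duty_ctrl)
    n <- min(nrow(sim), nrow(trace))
    sum((sim$T_water_C[1:n] - trace$T_water_C[1:n])^2 +
          (sim$T_plate_C[1:n] - trace$T_plate_C[1:n])^2)
  }
  res <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  est <- exp(res$par)
  names(est) <- fit
  list(estimates = est, convergence = res$convergence, rss = res$value)
}
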