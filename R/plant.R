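# Lumped first-order thermal model of the Peltier / slide / coverslip
# assembly. One thermal compartment: under a constant PWM drive u the
# plate relaxes exponentially toward ambient + gain * u with time
# constant tau. The device self-heats only (no heatsink, no active
# cooling); cooling is passive relaxation toward ambient at PWM = 0.

#' Thermal plant parameters
#'
#' @param gain Steady-state heating gain, degrees Celsius per PWM unit.
#'   The default 1.28 anchors the plant so that the PWM cap of 50 from a
#'   25 C ambient reaches 89 C, the device's maximum stable temperature.
#' @param tau_min Open-loop relaxation time constant in minutes
#'   (default 1.9, the passive-cooling constant of the device).
#' @param ambient_C Ambient temperature, degrees Celsius (default 25).
#' @param sensor_noise_sd Gaussian read noise of the thermistor channel,
#'   degrees Celsius (default 0.05).
#' @param process_noise_sd Random-walk process noise, degrees Celsius per
#'   sqrt(second) (default 0: the deterministic plant).
#' @param pwm_max Hardware PWM cap (default 50 out of a possible 255).
#'
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(gain = 1.28, tau_min = 1.9, ambient_C = 25,
                         sensor_noise_sd = 0.05, process_noise_sd = 0,
                         pwm_max = 50) {
  stopifnot(gain > 0, tau_min > 0, sensor_noise_sd >= 0,
            process_noise_sd >= 0, pwm_max > 0, pwm_max <= 255)
  structure(list(gain = gain, tau_min = tau_min, ambient_C = ambient_C,
                 sensor_noise_sd = sensor_noise_sd,
                 process_noise_sd = process_noise_sd, pwm_max = pwm_max),
            class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Thermal plant:\n")
  cat(sprintf("  gain %.3f C/PWM, tau %.2f min, ambient %.1f C\n",
              x$gain, x$tau_min, x$ambient_C))
  cat(sprintf("  sensor noise sd %.3f C, process noise sd %.3f C/sqrt(s), PWM cap %d\n",
              x$sensor_noise_sd, x$process_noise_sd, as.integer(x$pwm_max)))
  invisible(x)
}

#' Plant state
#'
#' @param time_s Elapsed time, seconds.
#' @param temperature_C True plate temperature, degrees Celsius.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(time_s = 0, temperature_C = 25) {
  stopifnot(is.finite(time_s), is.finite(temperature_C))
  structure(list(time_s = time_s, temperature_C = temperature_C),
            class = "plant_state")
}

#' Steady-state plate temperature at a constant PWM drive
#'
#' `ambient + gain * pwm`. With the default calibration and a 25 C
#' ambient, the PWM cap of 50 gives 89 C.
#'
#' @param params A `plant_params` object.
#' @param pwm PWM command in `[0, 255]`.
#' @return Temperature in degrees Celsius.
#' @export
steady_state_temp <- function(params, pwm) {
  stopifnot(inherits(params, "plant_params"))
  if (any(pwm < 0) || any(pwm > 255))
    stop("pwm must lie in [0, 255]")
  params$ambient_C + params$gain * pwm
}

#' Advance the plant by one exact first-order step
#'
#' The deterministic part is the closed-form solution of the first-order
#' ODE: `T(t + dt) = T_ss + (T(t) - T_ss) * exp(-dt/tau)` with
#' `T_ss = steady_state_temp(params, pwm)`. If `process_noise_sd > 0` a
#' Gaussian increment of sd `process_noise_sd * sqrt(dt)` is added; the
#' caller controls reproducibility through R's RNG state.
#'
#' @param state A `plant_state`.
#' @param params A `plant_params`.
#' @param pwm PWM command held over the step, in `[0, 255]`.
#' @param dt_s Step duration, seconds (>= 0).
#' @return The updated `plant_state`.
#' @export
step_plant <- function(state, params, pwm, dt_s) {
  stopifnot(inherits(state, "plant_state"), inherits(params, "plant_params"))
  if (dt_s < 0) stop("dt_s must be nonnegative")
  if (dt_s == 0) return(state)
  T_ss <- steady_state_temp(params, pwm)
  Tnew <- T_ss + (state$temperature_C - T_ss) * exp(-dt_s / (params$tau_min * 60))
  if (params$process_noise_sd > 0)
    Tnew <- Tnew + stats::rnorm(1L, 0, params$process_noise_sd * sqrt(dt_s))
  plant_state(state$time_s + dt_s, Tnew)
}

#' Read the simulated thermistor
#'
#' Returns the true plate temperature plus Gaussian read noise
#' (`sensor_noise_sd`). When a `thermistor_model` is supplied the reading
#' is round-tripped through the calibrated resistance relation
#' (temperature -> resistance -> temperature), exercising the same
#' conversion path a hardware ADC readout would.
#'
#' @param state A `plant_state`.
#' @param params A `plant_params`.
#' @param model Optional `thermistor_model` for the calibration round trip.
#' @return Measured temperature, degrees Celsius.
#' @export
read_sensor <- function(state, params, model = NULL) {
  stopifnot(inherits(state, "plant_state"), inherits(params, "plant_params"))
  Tm <- state$temperature_C
  if (params$sensor_noise_sd > 0)
    Tm <- Tm + stats::rnorm(1L, 0, params$sensor_noise_sd)
  if (!is.null(model))
    Tm <- resistance_to_temperature(model, temperature_to_resistance(model, Tm))
  Tm
}
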