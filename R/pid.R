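# Discrete PID controller with one-sided PWM clamping, the setpoint
# program engine, and the closed-loop simulation harness.
#
# The controller mirrors the microcontroller implementation: the error
# e = setpoint - measurement is sampled every 500 ms, the PWM output is
# an integer clamped to [0, pwm_max] (no active cooling: the lower clamp
# at 0 *is* passive cooling), the integral uses rectangular accumulation
# with conditional integration as anti-windup, and the derivative acts
# on the measurement to avoid setpoint kick on steps.

#' PID gains
#'
#' Units: `kp` in PWM units per degree C, `ki` in PWM units per
#' (degree C x second), `kd` in PWM units per (degree C / second).
#' `filter_s` is the time constant (seconds) of the first-order
#' low-pass applied to the measurement before the control law -- the
#' firmware ADC-averaging stage; it shapes the closed loop toward a
#' damped second-order response and suppresses read noise in the
#' derivative channel. Set it to 0 to act on raw readings.
#'
#' The defaults are the package's tuned controller constants, calibrated
#' once against the device's closed-loop behaviour (equilibration of
#' 25 C -> 27..45 C steps within 2 min into a +/-0.3 C band, hold
#' standard deviation below 0.2 C, a heating time constant near 0.6 min
#' on a 30 -> 37 C upshift, overshoot below 0.5 C) and then frozen.
#'
#' @param kp,ki,kd Nonnegative gains.
#' @param filter_s Measurement low-pass time constant, seconds (>= 0).
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 2.0, ki = 0.019, kd = 0, filter_s = 10) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, filter_s >= 0)
  structure(list(kp = kp, ki = ki, kd = kd, filter_s = filter_s),
            class = "pid_gains")
}

#' Controller state
#'
#' @param integral Accumulated error, degree C x seconds.
#' @param previous_measurement Last filtered reading (NA before the
#'   first sample; the derivative term is zero on the first step).
#' @param last_pwm Last commanded PWM.
#' @param carry Fractional PWM carried by the error-feedback quantizer.
#' @param filtered Current output of the measurement low-pass (NA before
#'   the first sample).
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(integral = 0, previous_measurement = NA_real_,
                             last_pwm = 0L, carry = 0, filtered = NA_real_) {
  structure(list(integral = integral,
                 previous_measurement = previous_measurement,
                 last_pwm = as.integer(last_pwm), carry = carry,
                 filtered = filtered),
            class = "controller_state")
}

#' One PID update
#'
#' Computes `e = setpoint - measurement`, the conditional-integration
#' integral and the measurement derivative, and returns the integer PWM
#' command clamped to `[0, pwm_max]`. While the output saturates in the
#' direction of the error the integral is frozen (anti-windup). The
#' integer output uses first-order error-feedback quantization: the
#' fractional remainder of each rounding is carried into the next
#' sample, so the time-averaged PWM equals the controller's continuous
#' demand and integer quantization cannot sustain a slow limit cycle.
#'
#' @param ctrl A `controller_state`.
#' @param gains A `pid_gains`.
#' @param setpoint_C,measurement_C Setpoint and measured temperature, C.
#' @param dt_s Controller sampling interval, seconds (> 0).
#' @param pwm_max Upper PWM clamp (default 50).
#' @return A list with elements `pwm` (integer) and `ctrl` (updated state).
#' @export
pid_step <- function(ctrl, gains, setpoint_C, measurement_C, dt_s,
                     pwm_max = 50) {
  stopifnot(inherits(ctrl, "controller_state"), inherits(gains, "pid_gains"))
  if (dt_s <= 0) stop("dt_s must be positive")
  filt <- if (is.na(ctrl$filtered) || gains$filter_s <= 0) measurement_C
          else ctrl$filtered +
            (1 - exp(-dt_s / gains$filter_s)) * (measurement_C - ctrl$filtered)
  e <- setpoint_C - filt
  deriv <- if (is.na(ctrl$previous_measurement)) 0
           else -(filt - ctrl$previous_measurement) / dt_s
  integral_new <- ctrl$integral + e * dt_s
  raw <- gains$kp * e + gains$ki * integral_new + gains$kd * deriv
  # anti-windup: if saturated in the direction of the error, keep the old
  # integral and recompute
  if ((raw > pwm_max && e > 0) || (raw < 0 && e < 0)) {
    integral_new <- ctrl$integral
    raw <- gains$kp * e + gains$ki * integral_new + gains$kd * deriv
  }
  pwm <- as.integer(max(0, min(pwm_max, floor(raw + ctrl$carry + 0.5))))
  carry_new <- if (raw >= 0 && raw <= pwm_max) raw + ctrl$carry - pwm else 0
  list(pwm = pwm,
       ctrl = controller_state(integral_new, filt, pwm, carry_new, filt))
}

# ---- setpoint programs ----------------------------------------------------

#' Setpoint program segments
#'
#' A setpoint program is an ordered list of segments, evaluated as a
#' piecewise-constant setpoint waveform:
#' \describe{
#'   \item{`seg_hold(target, duration_min)`}{hold `target` C for
#'     `duration_min` minutes.}
#'   \item{`seg_step(target, duration_min)`}{an instantaneous step to
#'     `target`, held for `duration_min` minutes (synonym of hold,
#'     named for readability of shift protocols).}
#'   \item{`seg_staircase(start, increment, dwell_min, end)`}{start at
#'     `start` C and increase by `increment` C every `dwell_min`
#'     minutes until `end` C is reached (the final level dwells too).}
#'   \item{`seg_oscillation(low, high, half_period_min, cycles)`}{`cycles`
#'     square-wave cycles alternating `high` then `low`, each level held
#'     for `half_period_min` minutes.}
#' }
#'
#' @param target,start,end,low,high Temperatures, degrees Celsius.
#' @param duration_min,dwell_min,half_period_min Durations, minutes (> 0).
#' @param increment Staircase increment, degrees Celsius (nonzero).
#' @param cycles Number of full oscillation cycles (>= 1).
#' @return A segment object usable in [setpoint_program()].
#' @name segments
NULL

#' @rdname segments
#' @export
seg_hold <- function(target, duration_min) {
  stopifnot(duration_min > 0)
  structure(list(type = "hold", target = target,
                 duration_s = duration_min * 60), class = "program_segment")
}

#' @rdname segments
#' @export
seg_step <- function(target, duration_min) {
  seg <- seg_hold(target, duration_min)
  seg$type <- "step"
  seg
}

#' @rdname segments
#' @export
seg_staircase <- function(start, increment, dwell_min, end) {
  stopifnot(dwell_min > 0, increment != 0, (end - start) / increment >= 0)
  n_levels <- floor((end - start) / increment) + 1L
  structure(list(type = "staircase", start = start, increment = increment,
                 dwell_s = dwell_min * 60, end = end,
                 duration_s = n_levels * dwell_min * 60),
            class = "program_segment")
}

#' @rdname segments
#' @export
seg_oscillation <- function(low, high, half_period_min, cycles) {
  stopifnot(half_period_min > 0, cycles >= 1, high > low)
  structure(list(type = "oscillation", low = low, high = high,
                 half_period_s = half_period_min * 60, cycles = as.integer(cycles),
                 duration_s = 2 * cycles * half_period_min * 60),
            class = "program_segment")
}

#' Assemble a setpoint program
#'
#' @param ... `program_segment` objects (see [segments]), in order.
#' @param sample_interval_s Controller sampling interval in seconds
#'   (default 0.5, the 500-ms readout cadence of the device).
#' @return An object of class `setpoint_program`.
#' @examples
#' setpoint_program(seg_hold(25, 2), seg_step(37, 20))
#' @export
setpoint_program <- function(..., sample_interval_s = 0.5) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1L]]) &&
      !inherits(segs[[1L]], "program_segment"))
    segs <- segs[[1L]]
  if (length(segs) == 0L) stop("program must contain at least one segment")
  ok <- vapply(segs, inherits, logical(1L), "program_segment")
  if (!all(ok)) stop("all program elements must be program segments")
  stopifnot(sample_interval_s > 0)
  structure(list(segments = segs, sample_interval_s = sample_interval_s,
                 duration_s = sum(vapply(segs, `[[`, numeric(1L), "duration_s"))),
            class = "setpoint_program")
}

#' Parse a compact waveform string into a setpoint program
#'
#' Grammar (segments separated by `,`; durations accept `s`, `m`, `h`
#' suffixes, default minutes):
#' `hold:<target>:<duration>` | `step:<target>:<duration>` |
#' `stair:<start>:<increment>:<dwell>:<end>` |
#' `osc:<low>:<high>:<half-period>:<cycles>`
#'
#' @param spec Waveform string, e.g. `"hold:25:2m,step:37:20m"` or
#'   `"osc:30:37:10m:3"`.
#' @param sample_interval_s Sampling interval, seconds.
#' @return A `setpoint_program`.
#' @export
parse_program <- function(spec, sample_interval_s = 0.5) {
  parse_dur <- function(x) {
    m <- regmatches(x, regexec("^([0-9.]+)([smh]?)$", x))[[1L]]
    if (length(m) == 0L) stop("cannot parse duration: ", x)
    v <- as.numeric(m[2L])
    switch(ifelse(m[3L] == "", "m", m[3L]), s = v / 60, m = v, h = v * 60)
  }
  segs <- lapply(strsplit(spec, ",", fixed = TRUE)[[1L]], function(s) {
    f <- strsplit(trimws(s), ":", fixed = TRUE)[[1L]]
    switch(f[1L],
      hold = seg_hold(as.numeric(f[2L]), parse_dur(f[3L])),
      step = seg_step(as.numeric(f[2L]), parse_dur(f[3L])),
      stair = seg_staircase(as.numeric(f[2L]), as.numeric(f[3L]),
                            parse_dur(f[4L]), as.numeric(f[5L])),
      osc = seg_oscillation(as.numeric(f[2L]), as.numeric(f[3L]),
                            parse_dur(f[4L]), as.integer(f[5L])),
      stop("unknown segment type: ", f[1L]))
  })
  setpoint_program(segs, sample_interval_s = sample_interval_s)
}

#' Evaluate the setpoint at a given time
#'
#' Piecewise-constant and right-continuous: at a segment boundary the new
#' segment's value applies. Oscillation segments start on the high level
#' (an upshift followed by passive cooling).
#'
#' @param program A `setpoint_program`.
#' @param t_s Time(s) since program start, seconds, within
#'   `[0, duration_s)`.
#' @return Setpoint(s), degrees Celsius.
#' @export
evaluate_program <- function(program, t_s) {
  stopifnot(inherits(program, "setpoint_program"))
  if (any(t_s < 0) || any(t_s >= program$duration_s))
    stop("t_s outside program range [0, ", program$duration_s, ")")
  eval_one <- function(t) {
    for (seg in program$segments) {
      if (t < seg$duration_s) {
        return(switch(seg$type,
          hold = ,
          step = seg$target,
          staircase = min(seg$start + seg$increment * floor(t / seg$dwell_s),
                          seg$end),
          oscillation = if (floor(t / seg$half_period_s) %% 2 == 0)
                          seg$high else seg$low))
      }
      t <- t - seg$duration_s
    }
  }
  vapply(t_s, eval_one, numeric(1L))
}

# ---- closed loop ----------------------------------------------------------

#' Run the closed temperature-control loop
#'
#' Iterates sensor readout -> PID update -> plant step at the program's
#' sampling interval and logs `(time, measured temperature, setpoint,
#' PWM)` at every sample, reproducing the CSV the device writes.
#'
#' @param params A `plant_params`.
#' @param gains A `pid_gains` (defaults to the tuned package gains).
#' @param program A `setpoint_program`.
#' @param model Optional `thermistor_model`; when given, sensor readings
#'   are round-tripped through the calibrated resistance relation.
#' @param start_temp_C Initial plate temperature (default: ambient).
#' @param warm_start When TRUE the integrator starts preloaded with the
#'   steady-state drive for the initial setpoint, as if the controller
#'   had already been holding it (avoids the cold-start dip when a run
#'   begins at its setpoint). Default FALSE: power-on state.
#' @param seed Optional integer seed; when supplied the run is
#'   bit-reproducible.
#' @return A [temperature_trace] data frame with columns
#'   `time_s`, `temp_C`, `setpoint_C`, `pwm`.
#' @examples
#' tr <- run_closed_loop(plant_params(sensor_noise_sd = 0),
#'                       program = setpoint_program(seg_hold(37, 5)))
#' @export
run_closed_loop <- function(params, gains = pid_gains(), program,
                            model = NULL, start_temp_C = NULL,
                            warm_start = FALSE, seed = NULL) {
  stopifnot(inherits(params, "plant_params"), inherits(gains, "pid_gains"),
            inherits(program, "setpoint_program"))
  if (!is.null(seed)) set.seed(seed)
  dt <- program$sample_interval_s
  n <- floor(program$duration_s / dt)
  if (n < 1L) stop("program shorter than one sampling interval")
  state <- plant_state(0, if (is.null(start_temp_C)) params$ambient_C
                          else start_temp_C)
  ctrl <- controller_state()
  tau_s <- params$tau_min * 60
  decay <- exp(-dt / tau_s)
  noise_p <- params$process_noise_sd * sqrt(dt)
  times <- (seq_len(n) - 1L) * dt
  setpoints <- evaluate_program(program, times)
  temps <- numeric(n)
  pwms <- integer(n)
  Tcur <- state$temperature_C
  integral <- if (warm_start && gains$ki > 0)
    (setpoints[1L] - params$ambient_C) / (params$gain * gains$ki) else 0
  prev_meas <- NA_real_; carry <- 0; filt <- NA_real_
  kp <- gains$kp; ki <- gains$ki; kd <- gains$kd
  alpha <- if (gains$filter_s > 0) 1 - exp(-dt / gains$filter_s) else 1
  pwm_max <- params$pwm_max
  sensor_sd <- params$sensor_noise_sd
  for (k in seq_len(n)) {
    meas <- Tcur
    if (sensor_sd > 0) meas <- meas + stats::rnorm(1L, 0, sensor_sd)
    if (!is.null(model))
      meas <- resistance_to_temperature(model,
                temperature_to_resistance(model, meas))
    filt <- if (is.na(filt)) meas else filt + alpha * (meas - filt)
    e <- setpoints[k] - filt
    deriv <- if (is.na(prev_meas)) 0 else -(filt - prev_meas) / dt
    int_new <- integral + e * dt
    raw <- kp * e + ki * int_new + kd * deriv
    if ((raw > pwm_max && e > 0) || (raw < 0 && e < 0)) {
      int_new <- integral
      raw <- kp * e + ki * int_new + kd * deriv
    }
    pwm <- max(0, min(pwm_max, floor(raw + carry + 0.5)))
    carry <- if (raw >= 0 && raw <= pwm_max) raw + carry - pwm else 0
    integral <- int_new; prev_meas <- filt
    temps[k] <- meas
    pwms[k] <- as.integer(pwm)
    # exact first-order step toward the steady state for this PWM
    T_ss <- params$ambient_C + params$gain * pwm
    Tcur <- T_ss + (Tcur - T_ss) * decay
    if (noise_p > 0) Tcur <- Tcur + stats::rnorm(1L, 0, noise_p)
  }
  temperature_trace(times, temps, setpoints, pwms)
}
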