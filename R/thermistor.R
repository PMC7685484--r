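# NTC thermistor beta-model calibration.
#
# The sensor follows the usual linearized NTC relation
#   1/T = A + ln(R)/B,   T in Kelvin, R in kilo-ohms,
# where B (Kelvin) is the beta parameter and A (1/K) the intercept.
# All arithmetic is done in Kelvin; the user-facing API speaks Celsius.

KELVIN_OFFSET <- 273.15

#' Calibration points for an NTC thermistor
#'
#' Bundles paired (temperature, resistance) measurements used to calibrate
#' the beta model of an NTC thermistor.
#'
#' @param temperature_C Numeric vector of temperatures in degrees Celsius.
#'   Must exceed absolute zero (-273.15 C).
#' @param resistance_kohm Numeric vector of resistances in kilo-ohms,
#'   strictly positive, same length as `temperature_C`.
#'
#' @return A data frame of class `calibration_points` with columns
#'   `temperature_C` and `resistance_kohm`.
#' @examples
#' calibration_points(c(4, 22, 30, 37), c(274, 114, 81, 60))
#' @export
calibration_points <- function(temperature_C, resistance_kohm) {
  if (length(temperature_C) != length(resistance_kohm))
    stop("temperature_C and resistance_kohm must have the same length")
  if (any(!is.finite(temperature_C)) || any(!is.finite(resistance_kohm)))
    stop("calibration points must be finite")
  if (any(temperature_C <= -KELVIN_OFFSET))
    stop("temperatures must exceed absolute zero (-273.15 C)")
  if (any(resistance_kohm <= 0))
    stop("resistances must be strictly positive")
  out <- data.frame(temperature_C = as.numeric(temperature_C),
                    resistance_kohm = as.numeric(resistance_kohm))
  class(out) <- c("calibration_points", "data.frame")
  out
}

#' Beta parameter from a pair of calibration measurements
#'
#' Estimates the NTC beta parameter from two (temperature, resistance)
#' measurements as `ln(R1/R2) / (1/T1 - 1/T2)` with temperatures in Kelvin.
#'
#' @param t1_C,t2_C Temperatures of the two measurements, degrees Celsius.
#' @param r1_kohm,r2_kohm Corresponding resistances, kilo-ohms.
#'
#' @return The beta estimate in Kelvin (scalar).
#' @examples
#' beta_from_pair(4, 274, 37, 60)   # about 3956 K
#' @export
beta_from_pair <- function(t1_C, r1_kohm, t2_C, r2_kohm) {
  if (r1_kohm <= 0 || r2_kohm <= 0)
    stop("resistances must be strictly positive")
  if (t1_C <= -KELVIN_OFFSET || t2_C <= -KELVIN_OFFSET)
    stop("temperatures must exceed absolute zero")
  if (t1_C == t2_C)
    stop("degenerate pair: calibration temperatures must differ")
  T1 <- t1_C + KELVIN_OFFSET
  T2 <- t2_C + KELVIN_OFFSET
  log(r1_kohm / r2_kohm) / (1 / T1 - 1 / T2)
}

#' Fit the beta model to a calibration table
#'
#' The beta parameter is the unweighted mean of [beta_from_pair()] over all
#' unordered pairs of points with distinct temperatures; the intercept is
#' the mean over points of `1/T - ln(R)/beta`. The nominal resistance at
#' 25 C is evaluated from the fitted relation as a convenience.
#'
#' @param points A `calibration_points` object (or data frame with columns
#'   `temperature_C`, `resistance_kohm`) holding at least two points at
#'   distinct temperatures.
#'
#' @return An object of class `thermistor_model` with elements `beta`
#'   (Kelvin), `intercept` (1/Kelvin), `reference_resistance_25C`
#'   (kilo-ohms) and `n_points`.
#' @examples
#' pts <- calibration_points(c(4, 22, 30, 37), c(274, 114, 81, 60))
#' fit_thermistor(pts)   # beta about 3950 K, R(25 C) about 100 kOhm
#' @export
fit_thermistor <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("temperature_C", "resistance_kohm") %in% names(points)))
    stop("points must have columns temperature_C and resistance_kohm")
  points <- calibration_points(points$temperature_C, points$resistance_kohm)
  n <- nrow(points)
  if (n < 2L || length(unique(points$temperature_C)) < 2L)
    stop("insufficient data: need >= 2 calibration points at distinct temperatures")
  pairs <- utils::combn(n, 2L)
  betas <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    if (points$temperature_C[i] == points$temperature_C[j]) return(NA_real_)
    beta_from_pair(points$temperature_C[i], points$resistance_kohm[i],
                   points$temperature_C[j], points$resistance_kohm[j])
  })
  beta <- mean(betas, na.rm = TRUE)
  TK <- points$temperature_C + KELVIN_OFFSET
  intercept <- mean(1 / TK - log(points$resistance_kohm) / beta)
  model <- structure(
    list(beta = beta, intercept = intercept,
         reference_resistance_25C = NA_real_, n_points = n),
    class = "thermistor_model")
  model$reference_resistance_25C <- temperature_to_resistance(model, 25)
  model
}

#' @export
print.thermistor_model <- function(x, ...) {
  cat("Thermistor beta model (1/T = A + ln(R)/B)\n")
  cat(sprintf("  B (beta): %.1f K\n", x$beta))
  cat(sprintf("  A (intercept): %.6g 1/K\n", x$intercept))
  cat(sprintf("  nominal R at 25 C: %.1f kOhm\n", x$reference_resistance_25C))
  cat(sprintf("  calibration points: %d\n", x$n_points))
  invisible(x)
}

#' Convert a measured resistance to temperature
#'
#' Inverts the calibrated relation: `T = 1 / (A + ln(R)/B)`, reported in
#' degrees Celsius. Strictly decreasing in resistance (NTC behaviour).
#'
#' @param model A `thermistor_model` from [fit_thermistor()].
#' @param resistance_kohm Resistance in kilo-ohms (vectorised, > 0).
#'
#' @return Temperature(s) in degrees Celsius.
#' @export
resistance_to_temperature <- function(model, resistance_kohm) {
  stopifnot(inherits(model, "thermistor_model"))
  if (any(resistance_kohm <= 0))
    stop("resistances must be strictly positive")
  1 / (model$intercept + log(resistance_kohm) / model$beta) - KELVIN_OFFSET
}

#' Predict the thermistor resistance at a given temperature
#'
#' Exact inverse of [resistance_to_temperature()]:
#' `R = exp(B * (1/T - A))` with T in Kelvin.
#'
#' @param model A `thermistor_model`.
#' @param temperature_C Temperature(s) in degrees Celsius (> -273.15).
#'
#' @return Resistance(s) in kilo-ohms.
#' @export
temperature_to_resistance <- function(model, temperature_C) {
  stopifnot(inherits(model, "thermistor_model"))
  if (any(temperature_C <= -KELVIN_OFFSET))
    stop("temperatures must exceed absolute zero")
  TK <- temperature_C + KELVIN_OFFSET
  exp(model$beta * (1 / TK - model$intercept))
}

#' Convert raw ADC counts from a voltage divider to resistance
#'
#' Optional plumbing for hardware logs: the thermistor sits in a divider
#' with a fixed resistor `r_divider_kohm` to ground, read by an ADC of
#' `adc_max` counts full scale. `R_therm = r_divider * (adc_max/counts - 1)`.
#'
#' @param counts ADC reading(s), in (0, adc_max).
#' @param r_divider_kohm Divider resistor in kilo-ohms (default 100).
#' @param adc_max Full-scale ADC count (default 1023, a 10-bit converter).
#'
#' @return Thermistor resistance(s) in kilo-ohms.
#' @export
adc_to_resistance <- function(counts, r_divider_kohm = 100, adc_max = 1023) {
  if (any(counts <= 0) || any(counts >= adc_max))
    stop("counts must lie strictly between 0 and adc_max")
  r_divider_kohm * (adc_max / counts - 1)
}

#' Read or write a calibration table as CSV
#'
#' Two-column CSV with header `temperature_C,resistance_kohm`.
#'
#' @param path File path.
#' @return For the reader, a `calibration_points` object.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("temperature_C", "resistance_kohm") %in% names(df)))
    stop("calibration CSV must have header temperature_C,resistance_kohm")
  calibration_points(df$temperature_C, df$resistance_kohm)
}

#' @rdname read_calibration_csv
#' @param points A `calibration_points` object to write.
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(
    data.frame(temperature_C = points$temperature_C,
               resistance_kohm = points$resistance_kohm),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The four-point bench calibration table used for the default sensor
#'
#' Resistances of the device's 100-kOhm NTC thermistor measured at 4, 22,
#' 30 and 37 C (274, 114, 81 and 60 kOhm).
#'
#' @return A `calibration_points` object with four rows.
#' @export
default_calibration_points <- function() {
  calibration_points(c(4, 22, 30, 37), c(274, 114, 81, 60))
}
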