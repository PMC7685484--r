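# Device trace logs and the trace-level statistics: binning, stability,
# equilibration time, and exponential heating/cooling time constants.

#' Temperature trace
#'
#' The logged record of a control run: one row per controller sample with
#' time (seconds), measured temperature, setpoint and PWM command --
#' the table the device writes to CSV.
#'
#' @param time_s Strictly increasing sample times, seconds.
#' @param temp_C Measured temperatures, degrees Celsius.
#' @param setpoint_C Setpoints, degrees Celsius.
#' @param pwm Integer PWM commands in `[0, 255]`.
#' @return A data frame of class `temperature_trace`.
#' @export
temperature_trace <- function(time_s, temp_C, setpoint_C, pwm) {
  n <- length(time_s)
  stopifnot(length(temp_C) == n, length(setpoint_C) == n, length(pwm) == n)
  if (n == 0L) stop("trace must contain at least one sample")
  if (any(diff(time_s) <= 0)) stop("trace time must be strictly increasing")
  if (any(pwm < 0 | pwm > 255)) stop("pwm must lie in [0, 255]")
  out <- data.frame(time_s = as.numeric(time_s), temp_C = as.numeric(temp_C),
                    setpoint_C = as.numeric(setpoint_C), pwm = as.integer(pwm))
  class(out) <- c("temperature_trace", "data.frame")
  out
}

#' Read / write a device trace CSV
#'
#' Comma-separated, UTF-8, '.' decimal, header
#' `time_s,temp_C,setpoint_C,pwm`. Reading validates monotone time and
#' the PWM range; malformed rows raise an error naming the line.
#'
#' @param path File path.
#' @return For the reader, a [temperature_trace].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, colClasses = "character"),
                 error = function(e) stop("cannot parse trace CSV: ",
                                          conditionMessage(e)))
  need <- c("time_s", "temp_C", "setpoint_C", "pwm")
  if (!all(need %in% names(df)))
    stop("trace CSV must have header time_s,temp_C,setpoint_C,pwm")
  if (nrow(df) == 0L) stop("trace CSV contains no samples")
  num <- lapply(need, function(col) suppressWarnings(as.numeric(df[[col]])))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad) > 0L)
    stop("malformed trace row at line ", bad[1L] + 1L)  # +1 for header
  temperature_trace(num[[1L]], num[[2L]], num[[3L]], num[[4L]])
}

#' @rdname read_trace_csv
#' @param trace A [temperature_trace] to write.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin a trace into fixed time windows
#'
#' Non-overlapping windows of `window_s` seconds starting at the first
#' sample; a partial final window is included.
#'
#' @param trace A [temperature_trace].
#' @param window_s Window width, seconds (default 60: 1-min binning).
#' @return A data frame with columns `bin_center_s`, `mean_C`, `sd_C`,
#'   `n` (sd is NA for single-sample bins).
#' @export
bin_trace <- function(trace, window_s = 60) {
  stopifnot(inherits(trace, "temperature_trace"), window_s > 0)
  idx <- floor((trace$time_s - trace$time_s[1L]) / window_s)
  agg <- lapply(split(trace$temp_C, idx), function(x)
    c(mean(x), stats::sd(x), length(x)))
  bins <- as.integer(names(agg))
  m <- do.call(rbind, agg)
  data.frame(bin_center_s = trace$time_s[1L] + (bins + 0.5) * window_s,
             mean_C = m[, 1L], sd_C = m[, 2L], n = as.integer(m[, 3L]),
             row.names = NULL)
}

#' Stability statistics of a controlled hold
#'
#' Computed on samples with `time_s >= after_s`: the mean and standard
#' deviation of the measured temperature, the maximum absolute deviation
#' from the setpoint, and the maximum of standard deviations over tiled
#' 3-min windows (the windowed control-error metric).
#'
#' @param trace A [temperature_trace].
#' @param after_s Discard samples before this time (seconds; default 0).
#' @param window_s Width of the tiled sd windows (default 180 s).
#' @return A list with `mean_C`, `sd_C`, `max_abs_error_C`,
#'   `max_windowed_sd_C`, `n`.
#' @export
stability_stats <- function(trace, after_s = 0, window_s = 180) {
  stopifnot(inherits(trace, "temperature_trace"))
  keep <- trace$time_s >= after_s
  if (!any(keep)) stop("no samples at or after after_s")
  x <- trace$temp_C[keep]
  sp <- trace$setpoint_C[keep]
  tt <- trace$time_s[keep]
  win <- floor((tt - tt[1L]) / window_s)
  wsd <- vapply(split(x, win), function(v)
    if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1L))
  list(mean_C = mean(x), sd_C = stats::sd(x),
       max_abs_error_C = max(abs(x - sp)),
       max_windowed_sd_C = suppressWarnings(max(wsd, na.rm = TRUE)),
       n = length(x))
}

#' Equilibration time of a shift
#'
#' The first time after which the measured temperature enters and
#' *remains* within `band` of `target` for all remaining samples,
#' reported in minutes relative to `from_s`. Returns `NA` when the band
#' is never held (not reached). The band test is applied to a short
#' rolling median of the readings (default 3 samples): at a 500-ms
#' sampling cadence no thermal excursion of a plant with a minutes-long
#' time constant lasts a single sample, so an isolated reading outside
#' the band is readout noise, not a loss of control.
#'
#' @param trace A [temperature_trace].
#' @param target Target temperature, degrees Celsius.
#' @param band Half-width of the tolerance band (default 0.3 C).
#' @param from_s Reference time of the shift (default: trace start).
#' @param median_window Rolling-median width in samples (odd; 1 disables
#'   the filter).
#' @return Minutes from `from_s` to permanent band entry, or `NA_real_`.
#' @export
equilibration_time <- function(trace, target, band = 0.3, from_s = NULL,
                               median_window = 3) {
  stopifnot(inherits(trace, "temperature_trace"), band > 0)
  if (is.null(from_s)) from_s <- trace$time_s[1L]
  keep <- trace$time_s >= from_s
  if (!any(keep)) stop("no samples at or after from_s")
  tt <- trace$time_s[keep]
  temps <- trace$temp_C[keep]
  if (median_window > 1L && length(temps) > median_window)
    temps <- stats::runmed(temps, median_window)
  ok <- abs(temps - target) <= band
  if (!ok[length(ok)]) return(NA_real_)
  last_bad <- max(c(0L, which(!ok)))
  if (last_bad == length(ok)) return(NA_real_)
  if (last_bad == 0L) return(0)
  (tt[last_bad + 1L] - from_s) / 60
}

# ---- exponential time-constant fits ---------------------------------------

# Normalize a segment to [0, 1]: baseline = mean of the baseline_s before
# t_start (falling back to the first sample when no earlier data exist),
# plateau = mean of the final plateau_s of the segment.
.normalize_segment <- function(trace, t_start, t_end, baseline_s, plateau_s,
                               min_delta) {
  seg <- trace$time_s >= t_start & trace$time_s <= t_end
  if (sum(seg) < 4L) stop("segment too short to fit")
  pre <- trace$time_s >= (t_start - baseline_s) & trace$time_s < t_start
  baseline <- if (any(pre)) mean(trace$temp_C[pre]) else trace$temp_C[seg][1L]
  base_se <- if (sum(pre) > 1L)
    stats::sd(trace$temp_C[pre]) / sqrt(sum(pre)) else 0
  tt <- trace$time_s[seg]
  in_pl <- tt >= (t_end - plateau_s)
  pl <- trace$temp_C[seg][in_pl]
  plat <- mean(pl)
  plat_se <- if (length(pl) > 1L) stats::sd(pl) / sqrt(length(pl)) else 0
  if (abs(plat - baseline) < min_delta)
    stop("degenerate segment: plateau indistinguishable from baseline")
  list(t_min = (tt - t_start) / 60, temps = trace$temp_C[seg],
       baseline = baseline, plateau = plat, plat_mean = plat,
       plat_t_min = (tt[in_pl] - t_start) / 60,
       base_se = base_se, plat_se = plat_se,
       y = (trace$temp_C[seg] - baseline) / (plat - baseline))
}

.fit_exp <- function(t_min, y, rising) {
  form <- if (rising) y ~ 1 - exp(-t_min / tau) else y ~ exp(-t_min / tau)
  # start from the observed 63% crossing of the normalized relaxation
  prog <- if (rising) y else 1 - y
  cross <- which(prog >= 1 - exp(-1))
  start_tau <- if (length(cross) > 0L && t_min[cross[1L]] > 0)
    t_min[cross[1L]] else max(diff(range(t_min)) / 5, 1e-3)
  fit <- minpack.lm::nlsLM(form, data = data.frame(t_min = t_min, y = y),
                           start = list(tau = start_tau),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- unname(stats::coef(fit)[["tau"]])
  se <- tryCatch(sqrt(stats::vcov(fit)[1L, 1L]), error = function(e) NA_real_)
  resid <- stats::resid(fit)
  list(tau = tau, se = se, rmse = sqrt(mean(resid^2)), n = length(y))
}

# Fit the normalized segment; the 95% CI combines the regression se with
# the sensitivity of tau to the estimated baseline and plateau levels
# (propagated by refitting at +1 se of each). The plateau window of a
# short segment still carries residual relaxation A*exp(-t/tau): its
# window mean M satisfies M = P + (B - P) * mean(exp(-t_w/tau)), so once
# tau is estimated the asymptote P is solved for and the fit repeated --
# this removes the truncation bias on exact exponentials.
.fit_segment <- function(nz, rising) {
  renorm <- function(base, plat) (nz$temps - base) / (plat - base)
  f0 <- .fit_exp(nz$t_min, nz$y, rising)
  # after the cooling-direction slot swap the asymptote lives in
  # `baseline` (the normalized signal decays to it); for rising fits it
  # is `plateau`
  for (it in 1:2) {
    m <- mean(exp(-nz$plat_t_min / f0$tau))
    if (!is.finite(m) || m >= 0.5) break
    other <- if (rising) nz$baseline else nz$plateau
    asym_new <- (nz$plat_mean - other * m) / (1 - m)
    if (rising) {
      if (abs(asym_new - nz$plateau) < 1e-12) break
      nz$plateau <- asym_new
    } else {
      if (abs(asym_new - nz$baseline) < 1e-12) break
      nz$baseline <- asym_new
    }
    nz$y <- renorm(nz$baseline, nz$plateau)
    f0 <- .fit_exp(nz$t_min, nz$y, rising)
  }
  dtau_b <- if (nz$base_se > 0)
    .fit_exp(nz$t_min, renorm(nz$baseline + nz$base_se, nz$plateau),
             rising)$tau - f0$tau else 0
  dtau_p <- if (nz$plat_se > 0)
    .fit_exp(nz$t_min, renorm(nz$baseline, nz$plateau + nz$plat_se),
             rising)$tau - f0$tau else 0
  se_tot <- sqrt(sum(c(f0$se, dtau_b, dtau_p)^2, na.rm = TRUE))
  structure(list(tau_min = f0$tau,
                 ci95_min = c(f0$tau - 1.96 * se_tot, f0$tau + 1.96 * se_tot),
                 rmse = f0$rmse, n = f0$n),
            class = "exp_fit_result")
}

#' @export
print.exp_fit_result <- function(x, ...) {
  cat(sprintf("tau = %.4g min (95%% CI %.4g-%.4g), rmse %.3g, n = %d\n",
              x$tau_min, x$ci95_min[1L], x$ci95_min[2L], x$rmse, x$n))
  invisible(x)
}

#' Fit heating / cooling time constants to a trace segment
#'
#' The segment `[t_start, t_end]` is normalized to `[0, 1]` using the
#' pre-shift baseline (mean of the `baseline_s` before `t_start`) and the
#' post-shift plateau (mean of the final `plateau_s` of the segment), and
#' the normalized relaxation is least-squares fitted with
#' `1 - exp(-t/tau)` (heating) or `exp(-t/tau)` (cooling). The fits are
#' invariant to affine transformations of the temperature scale.
#'
#' @param trace A [temperature_trace].
#' @param t_start,t_end Segment boundaries, seconds (the shift occurs at
#'   `t_start`).
#' @param baseline_s,plateau_s Averaging windows for the normalization
#'   (default 60 s each).
#' @param min_delta Minimum baseline-to-plateau excursion, degrees C;
#'   smaller excursions raise a degenerate-segment error (default 0.5).
#' @return An `exp_fit_result`: `tau_min` (minutes), `ci95_min`,
#'   `rmse` (normalized units), `n`.
#' @export
fit_heating_constant <- function(trace, t_start, t_end, baseline_s = 60,
                                 plateau_s = 60, min_delta = 0.5) {
  stopifnot(inherits(trace, "temperature_trace"), t_end > t_start)
  nz <- .normalize_segment(trace, t_start, t_end, baseline_s, plateau_s,
                           min_delta)
  fit <- .fit_segment(nz, rising = TRUE)
  if (mean(nz$y[nz$t_min >= max(nz$t_min) / 2]) < 0.5)
    warning("segment does not rise toward the plateau; fit may be unreliable")
  fit
}

#' @rdname fit_heating_constant
#' @export
fit_cooling_constant <- function(trace, t_start, t_end, baseline_s = 60,
                                 plateau_s = 60, min_delta = 0.5) {
  stopifnot(inherits(trace, "temperature_trace"), t_end > t_start)
  nz <- .normalize_segment(trace, t_start, t_end, baseline_s, plateau_s,
                           min_delta)
  # cooling: the normalized signal (T - plateau)/(baseline - plateau)
  # decays from 1 to 0, i.e. the normalization with the roles of the two
  # levels exchanged
  nz$y <- 1 - nz$y
  tmp <- nz$baseline; nz$baseline <- nz$plateau; nz$plateau <- tmp
  tmp <- nz$base_se; nz$base_se <- nz$plat_se; nz$plat_se <- tmp
  .fit_segment(nz, rising = FALSE)
}
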