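# Shared fixture builders. Everything is generated in code; seeds are
# fixed so the suite is deterministic.

# a constant-temperature device trace sampled like a movie would need it
constant_trace <- function(temp_C, duration_min, dt_s = 30, pwm = 9L) {
  tt <- seq(0, duration_min * 60, by = dt_s)
  temperature_trace(tt, rep(temp_C, length(tt)), rep(temp_C, length(tt)),
                    rep(pwm, length(tt)))
}

# an exact closed-form first-order approach trace: T(t) = target - dT*exp(-t/tau)
first_order_trace <- function(target, dT, tau_min, duration_min, dt_s = 0.5) {
  tt <- seq(0, duration_min * 60, by = dt_s)
  temps <- target - dT * exp(-tt / (tau_min * 60))
  temperature_trace(tt, temps, rep(target, length(tt)), rep(0L, length(tt)))
}

# a small wildtype movie at constant 37 C (about 10 s to simulate)
small_movie <- function(n_cells = 10, duration_min = 20, seed = 4,
                        drift = c(0.2, 0.3), noise_sd = 0.02,
                        phenotype = "wildtype", trace = NULL,
                        model = growth_model()) {
  if (is.null(trace)) trace <- constant_trace(37, duration_min + 2)
  cfg <- movie_config(trace, duration_min = duration_min,
                      dim_px = c(240, 760), seed = seed,
                      drift_px_per_frame = drift, noise_sd = noise_sd)
  set.seed(seed)
  cells <- cell_population(n_cells, model, frame_um(cfg),
                           temp_C = trace$temp_C[1L],
                           phenotype = phenotype,
                           col_spacing_um = 20, lane_spacing_um = 5)
  simulate_movie(cfg, model, cells)
}

# analytic spherocylinder boundary polygon (length pole-to-pole L, width w)
spherocylinder_contour <- function(L, w, n = 200, angle = 0, center = c(0, 0)) {
  r <- w / 2; a <- L / 2 - r
  th <- seq(-pi / 2, pi / 2, length.out = n %/% 4)
  right <- cbind(a + r * cos(th), r * sin(th))
  left <- cbind(-a - r * cos(th), r * sin(rev(th)))
  top <- cbind(seq(a, -a, length.out = n %/% 4), r)
  bottom <- cbind(seq(-a, a, length.out = n %/% 4), -r)
  pts <- rbind(right, top, left, bottom)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  pts <- pts %*% t(R)
  cbind(row = pts[, 2L] + center[1L], col = pts[, 1L] + center[2L])
}
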