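# Temperature-responsive single-cell growth model and population
# dynamics for the synthetic time-lapse generator.
#
# Cells are spherocylinders growing exponentially in length at a
# per-cell instantaneous rate that relaxes toward a temperature-
# dependent steady-state rate. The relaxation is slow on the first
# temperature shift and fast on subsequent ones (physiological
# adaptation within one oscillatory period). Division is symmetric with
# small noise; temperature-sensitive phenotypes (filamentation,
# rounding, shrinkage) activate above a nonpermissive temperature.

#' Growth model
#'
#' @param rate_map Data frame with columns `temp_C`, `rate_per_h`
#'   defining the steady-state elongation rate; interpolated linearly,
#'   clamped (with a warning) outside its range. Defaults anchor
#'   1.4 1/h at 30 C and 1.98 1/h at 37 C.
#' @param adaptation_tau_first_min Relaxation time constant of the
#'   instantaneous rate on the first temperature shift, minutes
#'   (default 24: a 30->37 C upshift raises the rate by only ~14%
#'   after 10 min).
#' @param adaptation_tau_later_min Relaxation time constant on later
#'   shifts, minutes (default 2.5: steady state regained within
#'   7-8 min). Must not exceed `adaptation_tau_first_min`.
#' @param division_length_mean_um,division_cv Mean and coefficient of
#'   variation of the per-cell division length threshold (um).
#' @param division_asym_sd Standard deviation of the division asymmetry
#'   (daughter fraction drawn from N(0.5, this); default 0.015, i.e.
#'   symmetric within ~3%).
#' @param width_um Resting cell width (um).
#' @param rate_cv Cell-to-cell lognormal variability of the growth-rate
#'   scale factor (default 0.05).
#' @param nonpermissive_C Temperature above which ts phenotypes express
#'   (default 40).
#' @param shrink_rate_per_h Fractional cross-sectional area loss rate of
#'   the shrinking phenotype (default 0.3/h).
#' @param daughter_gap_um Visible gap opened between daughter poles at
#'   division (default 0.25 um).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(rate_map = data.frame(temp_C = c(30, 37),
                                               rate_per_h = c(1.4, 1.98)),
                         adaptation_tau_first_min = 24,
                         adaptation_tau_later_min = 2.5,
                         division_length_mean_um = 5,
                         division_cv = 0.08,
                         division_asym_sd = 0.015,
                         width_um = 0.9,
                         rate_cv = 0.05,
                         nonpermissive_C = 40,
                         shrink_rate_per_h = 0.3,
                         daughter_gap_um = 0.25) {
  stopifnot(is.data.frame(rate_map),
            all(c("temp_C", "rate_per_h") %in% names(rate_map)),
            nrow(rate_map) >= 2, all(rate_map$rate_per_h > 0),
            !is.unsorted(rate_map$temp_C, strictly = TRUE),
            !is.unsorted(rate_map$rate_per_h),
            adaptation_tau_later_min <= adaptation_tau_first_min,
            adaptation_tau_later_min > 0,
            division_length_mean_um > 0, division_cv >= 0, width_um > 0,
            shrink_rate_per_h >= 0)
  structure(list(rate_map = rate_map,
                 adaptation_tau_first_min = adaptation_tau_first_min,
                 adaptation_tau_later_min = adaptation_tau_later_min,
                 division_length_mean_um = division_length_mean_um,
                 division_cv = division_cv,
                 division_asym_sd = division_asym_sd,
                 width_um = width_um, rate_cv = rate_cv,
                 nonpermissive_C = nonpermissive_C,
                 shrink_rate_per_h = shrink_rate_per_h,
                 daughter_gap_um = daughter_gap_um),
            class = "growth_model")
}

#' Steady-state elongation rate at a temperature
#'
#' Linear interpolation of the model's rate map; temperatures outside
#' the map's range are clamped to its endpoints with a warning.
#'
#' @param model A `growth_model`.
#' @param temp_C Temperature(s), degrees Celsius.
#' @return Elongation rate(s), 1/h.
#' @export
target_rate <- function(model, temp_C) {
  stopifnot(inherits(model, "growth_model"))
  rng <- range(model$rate_map$temp_C)
  # sensor jitter of a few tenths of a degree around an anchor is routine;
  # warn only for substantive excursions
  if (any(temp_C < rng[1L] - 0.5 | temp_C > rng[2L] + 0.5))
    warning("temperature outside the rate map range [", rng[1L], ", ",
            rng[2L], "] C; rate clamped")
  stats::approx(model$rate_map$temp_C, model$rate_map$rate_per_h,
                xout = pmin(pmax(temp_C, rng[1L]), rng[2L]),
                rule = 2)$y
}

#' First-order relaxation of the instantaneous growth rate
#'
#' Relaxes `current_rate` toward the steady-state rate at `temp_C` with
#' time constant `adaptation_tau_first_min` while the population is
#' responding to its first temperature shift in the given direction
#' (`shift_count <= 1`) and `adaptation_tau_later_min` on subsequent
#' shifts.
#'
#' @param current_rate Instantaneous rate(s), 1/h.
#' @param model A `growth_model`.
#' @param temp_C Current temperature, degrees Celsius.
#' @param dt_min Time step, minutes (> 0).
#' @param shift_count How many shifts in this direction the population
#'   has experienced (0 or 1: slow first response; >= 2: adapted).
#' @param rate_factor Optional per-cell scale factor(s) on the target.
#' @return Updated rate(s), 1/h.
#' @export
relax_rate <- function(current_rate, model, temp_C, dt_min, shift_count = 1,
                       rate_factor = 1) {
  stopifnot(inherits(model, "growth_model"), dt_min > 0)
  tau <- if (shift_count <= 1) model$adaptation_tau_first_min
         else model$adaptation_tau_later_min
  tgt <- target_rate(model, temp_C) * rate_factor
  tgt + (current_rate - tgt) * exp(-dt_min / tau)
}

#' Seed an initial cell population
#'
#' Cells are laid out on a staggered grid of horizontal lanes with a
#' small random orientation jitter, so that lineages growing end-to-end
#' stay resolvable for the full movie; phase-contrast time-lapse
#' benchmarks of sessile rods on agarose justify the sessile layout.
#'
#' @param n Number of cells.
#' @param model A `growth_model`.
#' @param frame_um Frame size as `c(width_um, height_um)`.
#' @param temp_C Temperature at which the population is at steady state.
#' @param phenotype One of `"wildtype"`, `"filamentous"`, `"rounding"`,
#'   `"shrinking"` applied to all cells.
#' @param length_range_um Range of initial lengths (uniform draw).
#' @param col_spacing_um,lane_spacing_um Grid spacing (um).
#' @param angle_jitter_deg Orientation jitter half-range (degrees).
#' @return A data frame of class `cell_population`; one row per cell
#'   with geometry, instantaneous rate and lineage fields.
#' @export
cell_population <- function(n, model, frame_um, temp_C = 37,
                            phenotype = c("wildtype", "filamentous",
                                          "rounding", "shrinking"),
                            length_range_um = c(2.2, 4.2),
                            col_spacing_um = 20, lane_spacing_um = 4.2,
                            angle_jitter_deg = 4) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(model, "growth_model"), n >= 1, length(frame_um) == 2)
  ncol_grid <- max(1L, floor((frame_um[1L] - col_spacing_um / 2) /
                               col_spacing_um))
  nrow_grid <- ceiling(n / ncol_grid)
  if (nrow_grid * lane_spacing_um > frame_um[2L] - lane_spacing_um / 2)
    stop("frame too small for ", n, " cells at the given spacing")
  idx <- seq_len(n) - 1L
  gx <- (idx %% ncol_grid + 0.5) * col_spacing_um +
    stats::runif(n, -1, 1)
  gy <- (idx %/% ncol_grid + 1) * lane_spacing_um +
    stats::runif(n, -0.5, 0.5)
  tgt <- target_rate(model, temp_C)
  factor <- exp(stats::rnorm(n, 0, model$rate_cv))
  out <- data.frame(
    id = seq_len(n), parent = NA_integer_, root = seq_len(n),
    x_um = gx, y_um = gy,
    angle = stats::runif(n, -angle_jitter_deg, angle_jitter_deg) * pi / 180,
    length_um = stats::runif(n, length_range_um[1L], length_range_um[2L]),
    width_um = model$width_um,
    rate_per_h = tgt * factor, rate_factor = factor,
    div_threshold_um = stats::rnorm(
      n, model$division_length_mean_um,
      model$division_cv * model$division_length_mean_um),
    phenotype = phenotype, stringsAsFactors = FALSE)
  class(out) <- c("cell_population", "data.frame")
  out
}

#' Advance a population by one time step
#'
#' Lengths multiply by `exp(rate * dt)`. Wildtype cells (and ts mutants
#' below the nonpermissive temperature) divide when their length exceeds
#' the per-cell threshold: division is symmetric within noise, conserves
#' total length, and places the daughters end-to-end along the mother's
#' axis separated by a small gap. Above the nonpermissive temperature,
#' filamentous cells elongate without dividing, rounding cells transfer
#' elongation into width until the aspect ratio approaches 1, and
#' shrinking cells lose cross-sectional area exponentially.
#'
#' @param cells A `cell_population`.
#' @param model A `growth_model`.
#' @param temp_C Current temperature, degrees Celsius.
#' @param dt_s Time step, seconds.
#' @return The updated `cell_population` (possibly with more rows).
#' @export
advance_population <- function(cells, model, temp_C, dt_s) {
  stopifnot(inherits(cells, "cell_population"), inherits(model, "growth_model"),
            dt_s >= 0)
  if (nrow(cells) == 0L || dt_s == 0) return(cells)
  dt_h <- dt_s / 3600
  np <- temp_C >= model$nonpermissive_C
  grow <- exp(cells$rate_per_h * dt_h)
  pheno <- cells$phenotype
  len <- cells$length_um; wid <- cells$width_um
  elong <- if (np) pheno %in% c("wildtype", "filamentous") else
    rep(TRUE, length(len))
  len[elong] <- len[elong] * grow[elong]
  if (np) {
    # rounding: elongation flux diverted into width until the cell is
    # round, then slow isotropic growth
    ro <- pheno == "rounding"
    ro_w <- ro & wid < 0.95 * len
    wid[ro_w] <- pmin(wid[ro_w] * grow[ro_w]^2, len[ro_w])
    ro_i <- ro & !ro_w
    len[ro_i] <- len[ro_i] * grow[ro_i]^(1 / 3)
    wid[ro_i] <- pmin(wid[ro_i] * grow[ro_i]^(1 / 3), len[ro_i])
    sh <- pheno == "shrinking"
    shr <- exp(-model$shrink_rate_per_h * dt_h / 2)
    len[sh] <- pmax(len[sh] * shr, 0.4)
    wid[sh] <- pmax(wid[sh] * shr, 0.3)
  }
  cells$length_um <- len; cells$width_um <- wid
  # division: wildtype always; ts mutants only below nonpermissive T
  can_divide <- pheno == "wildtype" | (!np & pheno == "filamentous")
  div <- which(can_divide & cells$length_um > cells$div_threshold_um)
  if (length(div) == 0L) return(.relayout_chains(cells, model))
  next_id <- max(cells$id) + 1L
  daughters <- vector("list", 2L * length(div))
  for (k in seq_along(div)) {
    i <- div[k]
    L <- cells$length_um[i]
    f <- min(max(stats::rnorm(1L, 0.5, model$division_asym_sd), 0.35), 0.65)
    l1 <- f * L; l2 <- (1 - f) * L
    ux <- cos(cells$angle[i]); uy <- sin(cells$angle[i])
    gap <- model$daughter_gap_um / 2
    mk <- function(id, len, off) {
      d <- cells[i, ]
      d$id <- id; d$parent <- cells$id[i]
      d$length_um <- len
      d$x_um <- cells$x_um[i] + ux * off
      d$y_um <- cells$y_um[i] + uy * off
      d$rate_factor <- cells$rate_factor[i] * exp(stats::rnorm(1L, 0, 0.02))
      d$rate_per_h <- cells$rate_per_h[i] * d$rate_factor /
        cells$rate_factor[i]
      d$div_threshold_um <- stats::rnorm(
        1L, model$division_length_mean_um,
        model$division_cv * model$division_length_mean_um)
      d
    }
    daughters[[2L * k - 1L]] <- mk(next_id, l1, -(L - l1) / 2 - gap)
    daughters[[2L * k]] <- mk(next_id + 1L, l2, (L - l2) / 2 + gap)
    next_id <- next_id + 2L
  }
  out <- rbind(cells[-div, ], do.call(rbind, daughters))
  rownames(out) <- NULL
  class(out) <- c("cell_population", "data.frame")
  .relayout_chains(out, model)
}

# Cells descended from one founder stay collinear and push each other
# apart as they elongate: each founder's chain is re-laid out along its
# axis with a constant pole-to-pole gap, preserving the chain's
# length-weighted center of mass (what growing rods do on a pad).
.relayout_chains <- function(cells, model) {
  gap <- model$daughter_gap_um
  for (rt in unique(cells$root)) {
    i <- which(cells$root == rt)
    if (length(i) < 2L) next
    ux <- cos(cells$angle[i[1L]]); uy <- sin(cells$angle[i[1L]])
    w <- cells$length_um[i]
    cx <- sum(cells$x_um[i] * w) / sum(w)
    cy <- sum(cells$y_um[i] * w) / sum(w)
    s <- (cells$x_um[i] - cx) * ux + (cells$y_um[i] - cy) * uy
    ord <- order(s)
    L <- cells$length_um[i][ord]
    extent <- sum(L) + gap * (length(i) - 1L)
    pole <- -extent / 2
    centers <- numeric(length(i))
    for (k in seq_along(ord)) {
      centers[k] <- pole + L[k] / 2
      pole <- pole + L[k] + gap
    }
    # shift so the length-weighted center of mass is preserved
    centers <- centers - sum(centers * L) / sum(L)
    cells$x_um[i[ord]] <- cx + centers * ux
    cells$y_um[i[ord]] <- cy + centers * uy
  }
  cells
}

#' Area fraction occupied by the population
#'
#' Approximates each cell's footprint as `length x width` and reports
#' the fraction of the frame covered. Analysis flags switch off once
#' this exceeds the crowding threshold (population growth inhibition).
#'
#' @param cells A `cell_population`.
#' @param frame_um Frame size `c(width_um, height_um)`.
#' @return Scalar fraction in `[0, 1]`.
#' @export
area_fraction <- function(cells, frame_um) {
  sum(cells$length_um * cells$width_um) / (frame_um[1L] * frame_um[2L])
}
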