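# Phase-contrast-like rendering of spherocylindrical cells and the
# movie simulation driver.
#
# Cells render as dark bodies with a bright halo on a mid-gray
# background -- the visual signature of phase contrast. Edges are
# smoothstepped over ~1 px, so cell boundaries are defined at subpixel
# resolution; Gaussian read noise is added per pixel. Pixel coordinates
# are R-native: 1-based (row, column), row increasing downward.

#' Movie configuration
#'
#' @param frame_interval_s Seconds between frames (default 30).
#' @param pixel_size_um Physical pixel size (default 0.11, a 40X
#'   objective with a 1.5X tube lens on a 6.5-um camera).
#' @param dim_px Image size `c(rows, cols)`.
#' @param noise_sd Gaussian pixel noise sd in intensity units
#'   (images span [0, 1]; default 0.02).
#' @param drift_px_per_frame Global stage drift per frame,
#'   `c(row, col)` pixels (default `c(0.2, 0.3)`).
#' @param trace A [temperature_trace] driving growth; must cover the
#'   movie duration.
#' @param duration_min Movie length, minutes.
#' @param crowding_limit Area fraction above which cells stop being
#'   flagged analyzable (default 0.3).
#' @param seed Integer seed; the movie is fully reproducible under it.
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(trace, duration_min, frame_interval_s = 30,
                         pixel_size_um = 0.11, dim_px = c(424, 1920),
                         noise_sd = 0.02, drift_px_per_frame = c(0.2, 0.3),
                         crowding_limit = 0.3, seed = 1) {
  stopifnot(inherits(trace, "temperature_trace"), frame_interval_s > 0,
            duration_min > 0, pixel_size_um > 0, length(dim_px) == 2,
            noise_sd >= 0)
  if (max(trace$time_s) < duration_min * 60 - frame_interval_s)
    stop("temperature trace shorter than the movie duration")
  structure(list(trace = trace, duration_min = duration_min,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, dim_px = as.integer(dim_px),
                 noise_sd = noise_sd,
                 drift_px_per_frame = drift_px_per_frame,
                 crowding_limit = crowding_limit, seed = seed),
            class = "movie_config")
}

#' Frame size in micrometres implied by a movie configuration
#' @param config A `movie_config`.
#' @return `c(width_um, height_um)` (columns, rows).
#' @export
frame_um <- function(config) {
  c(config$dim_px[2L], config$dim_px[1L]) * config$pixel_size_um
}

# smoothstep weight: 1 well inside (d << 0), 0 well outside, linear ramp
# of width `edge` around 0
.edge_ramp <- function(d, edge) pmin(pmax(0.5 - d / edge, 0), 1)

#' Render one phase-contrast frame
#'
#' Each cell is a spherocylinder: the set of points within
#' `width_um / 2` of its axial core segment. Pixels get a dark body
#' intensity, a bright halo ring just outside the boundary, and
#' smoothstepped edges; the whole field is offset by the cumulative
#' stage drift, then Gaussian noise is added.
#'
#' @param cells A `cell_population`.
#' @param config A `movie_config`.
#' @param drift_px Cumulative drift offset `c(row, col)` in pixels.
#' @param background,body,halo Intensities in [0, 1].
#' @return A list with `image` (matrix in [0, 1], `dim_px`) and
#'   `truth` (data frame: one row per rendered cell with pixel-frame
#'   centroid, geometry in um, rate and phenotype).
#' @export
render_frame <- function(cells, config, drift_px = c(0, 0),
                         background = 0.5, body = 0.28, halo = 0.62) {
  px <- config$pixel_size_um
  nr <- config$dim_px[1L]; nc <- config$dim_px[2L]
  img <- matrix(background, nr, nc)
  halo_w <- 0.25 / px     # halo ring width, px
  edge <- 1               # edge ramp width, px
  n <- nrow(cells)
  if (n > 0L) for (i in seq_len(n)) {
    # cell geometry in pixel units, drift applied
    cx <- cells$x_um[i] / px + drift_px[2L]
    cy <- cells$y_um[i] / px + drift_px[1L]
    r <- cells$width_um[i] / 2 / px
    a <- max(cells$length_um[i] / 2 / px - r, 0)  # half core length
    ux <- cos(cells$angle[i]); uy <- sin(cells$angle[i])
    pad <- r + halo_w + 2
    ext <- a * abs(ux) + pad
    eyt <- a * abs(uy) + pad
    rows <- max(1L, floor(cy - eyt)):min(nr, ceiling(cy + eyt))
    cols <- max(1L, floor(cx - ext)):min(nc, ceiling(cx + ext))
    if (length(rows) == 0L || length(cols) == 0L) next
    dx <- rep(cols - cx, each = length(rows))
    dy <- rep(rows - cy, times = length(cols))
    # distance to the core segment
    s <- pmin(pmax(dx * ux + dy * uy, -a), a)
    d <- sqrt((dx - s * ux)^2 + (dy - s * uy)^2) - r
    wb <- .edge_ramp(d, edge)                       # body weight
    wh <- .edge_ramp(abs(d - halo_w / 2 - edge / 2) - halo_w / 2, edge)
    wh <- wh * (1 - wb)                             # halo outside body
    sub <- img[rows, cols]
    sub <- sub * (1 - wb - wh) + body * wb + halo * wh
    img[rows, cols] <- sub
  }
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 1)
  truth <- data.frame(
    id = cells$id, parent = cells$parent,
    row_px = cells$y_um / px + drift_px[1L],
    col_px = cells$x_um / px + drift_px[2L],
    length_um = cells$length_um, width_um = cells$width_um,
    rate_per_h = cells$rate_per_h, phenotype = cells$phenotype,
    stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Simulate a ground-truthed time-lapse movie
#'
#' Drives the growth model from the temperature trace frame by frame:
#' the instantaneous rate of every cell relaxes toward the steady-state
#' rate at the trace's measured temperature (slowly on the first shift
#' in each direction, quickly on later ones -- shifts are detected from
#' the trace's setpoint channel), the population is advanced (growth,
#' division, phenotypes), and each frame is rendered with cumulative
#' stage drift.
#'
#' @param config A `movie_config`.
#' @param model A `growth_model`.
#' @param cells Initial `cell_population` (default: 100 wildtype cells
#'   seeded at the trace's initial temperature).
#' @return A list of class `synthetic_movie`: `frames` (list of
#'   matrices), `truth` (per-frame ground-truth table with `frame`,
#'   `time_min`, `temp_C`, `analyzable` columns appended),
#'   `drift` (cumulative per-frame offsets), `config`, `model`.
#' @export
simulate_movie <- function(config, model = growth_model(), cells = NULL) {
  stopifnot(inherits(config, "movie_config"), inherits(model, "growth_model"))
  set.seed(config$seed)
  dt_s <- config$frame_interval_s
  n_frames <- floor(config$duration_min * 60 / dt_s) + 1L
  tr <- config$trace
  temp_at <- function(t_s) {
    i <- findInterval(t_s, tr$time_s)
    tr$temp_C[max(i, 1L)]
  }
  sp_at <- function(t_s) {
    i <- findInterval(t_s, tr$time_s)
    tr$setpoint_C[max(i, 1L)]
  }
  if (is.null(cells))
    cells <- cell_population(100, model, frame_um(config),
                             temp_C = temp_at(0))
  up_count <- 0L; down_count <- 0L; last_dir <- 0L
  sp_prev <- sp_at(0)
  truth <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  drift <- matrix(0, n_frames, 2L,
                  dimnames = list(NULL, c("row_px", "col_px")))
  analyzable <- TRUE
  for (k in seq_len(n_frames)) {
    t_s <- (k - 1L) * dt_s
    Tnow <- temp_at(t_s)
    sp <- sp_at(t_s)
    if (sp > sp_prev + 1e-9) { up_count <- up_count + 1L; last_dir <- 1L }
    if (sp < sp_prev - 1e-9) { down_count <- down_count + 1L; last_dir <- -1L }
    sp_prev <- sp
    if (k > 1L) {
      shift_count <- if (last_dir >= 0L) up_count else down_count
      cells$rate_per_h <- relax_rate(cells$rate_per_h, model, Tnow,
                                     dt_s / 60, max(shift_count, 1L),
                                     cells$rate_factor)
      cells <- advance_population(cells, model, Tnow, dt_s)
      drift[k, ] <- drift[k - 1L, ] + config$drift_px_per_frame
    }
    if (analyzable &&
        area_fraction(cells, frame_um(config)) > config$crowding_limit)
      analyzable <- FALSE
    fr <- render_frame(cells, config, drift_px = drift[k, ])
    frames[[k]] <- fr$image
    tt <- fr$truth
    tt$frame <- k; tt$time_min <- t_s / 60; tt$temp_C <- Tnow
    tt$analyzable <- analyzable
    truth[[k]] <- tt
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(frames = frames, truth = truth,
                 drift = drift, config = config, model = model),
            class = "synthetic_movie")
}

#' Write a synthetic movie to disk
#'
#' The image stack goes to a multi-page 8-bit grayscale TIFF and the
#' ground truth to CSV (columns: frame, time_min, temp_C, id, parent,
#' row_px, col_px, length_um, width_um, rate_per_h, phenotype,
#' analyzable).
#'
#' @param movie A `synthetic_movie`.
#' @param tiff_path,truth_path Output paths.
#' @return Invisibly, the TIFF path.
#' @export
write_movie <- function(movie, tiff_path, truth_path = NULL) {
  stopifnot(inherits(movie, "synthetic_movie"))
  tiff::writeTIFF(movie$frames, tiff_path, bits.per.sample = 8L,
                  compression = "none")
  if (!is.null(truth_path))
    utils::write.csv(movie$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(tiff_path)
}

#' Read an image stack from a multi-page TIFF
#'
#' @param path TIFF file.
#' @return List of grayscale matrices in [0, 1] (multi-channel pages are
#'   averaged to grayscale).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1L, 2L), mean)
    p
  })
}
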