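# Synthetic time-lapse generator: growth model, population dynamics,
# rendering.

test_that("the rate map anchors and interpolates monotonically", {
  m <- growth_model()
  expect_equal(target_rate(m, 37), 1.98)
  expect_equal(target_rate(m, 30), 1.4)
  expect_equal(target_rate(m, 33.5), (1.4 + 1.98) / 2)
  temps <- seq(30, 37, by = 0.25)
  expect_true(all(diff(target_rate(m, temps)) >= 0))
  expect_warning(r <- target_rate(m, 20), "clamped")
  expect_equal(r, 1.4)
})

test_that("rate adaptation is slow on the first shift, fast afterwards", {
  m <- growth_model()
  # already at target: unchanged
  expect_equal(relax_rate(1.98, m, 37, 1, shift_count = 1), 1.98)
  # dt -> infinity converges to the target
  expect_equal(relax_rate(1.4, m, 37, 1e6, shift_count = 1), 1.98)
  # first 30->37 upshift: ~14% rate gain after 10 min
  r <- 1.4
  for (i in 1:20) r <- relax_rate(r, m, 37, 0.5, shift_count = 1)
  expect_equal(r / 1.4 - 1, 0.14, tolerance = 0.05)
  # second upshift: within 5% of steady state after 7.5 min
  r2 <- 1.4
  for (i in 1:15) r2 <- relax_rate(r2, m, 37, 0.5, shift_count = 2)
  expect_gt(r2, 0.95 * 1.98)
})

test_that("exponential elongation and division conserve biomass", {
  m <- growth_model(division_length_mean_um = 1e6)   # no divisions
  cells <- cell_population(5, m, c(100, 30), temp_C = 37,
                           col_spacing_um = 18, lane_spacing_um = 5)
  lam <- 1.5
  cells$rate_per_h <- lam
  t_double_s <- log(2) / lam * 3600
  out <- cells
  for (i in 1:10) out <- advance_population(out, m, 37, t_double_s / 10)
  expect_equal(out$length_um, 2 * cells$length_um, tolerance = 1e-10)
  # with a finite threshold, divisions conserve total length
  m2 <- growth_model()
  set.seed(5)
  pop <- cell_population(8, m2, c(160, 40), temp_C = 37,
                         col_spacing_um = 18, lane_spacing_um = 4.5)
  before <- pop
  stepped <- advance_population(before, m2, 37, 30)
  grown_total <- sum(before$length_um * exp(before$rate_per_h * 30 / 3600))
  expect_equal(sum(stepped$length_um), grown_total, tolerance = 1e-9)
  # population can only grow (no lysis modes here)
  expect_gte(nrow(stepped), nrow(pop))
})

test_that("filamentous cells stop dividing and quadruple length in 75 min", {
  m <- growth_model()
  cells <- cell_population(6, m, c(220, 40), temp_C = 30,
                           phenotype = "filamentous",
                           col_spacing_um = 35, lane_spacing_um = 5)
  cells$rate_per_h <- 1.1
  cells$rate_factor <- 1
  out <- cells
  for (i in 1:150) out <- advance_population(out, m, 42, 30)  # T > 40 C
  expect_identical(nrow(out), nrow(cells))                    # no divisions
  expect_equal(mean(out$length_um / cells$length_um), 4, tolerance = 0.02)
})

test_that("nonpermissive phenotypes reshape cells as configured", {
  m <- growth_model()
  mk <- function(ph) {
    p <- cell_population(1, m, c(60, 30), temp_C = 37, phenotype = ph,
                         col_spacing_um = 25, lane_spacing_um = 8)
    p$length_um <- 3; p$rate_per_h <- 1.5
    p
  }
  ro <- mk("rounding")
  for (i in 1:120) ro <- advance_population(ro, m, 42, 30)
  expect_gt(ro$width_um / ro$length_um, 0.9)    # aspect ratio -> 1
  sh <- mk("shrinking")
  for (i in 1:120) sh <- advance_population(sh, m, 42, 30)
  expect_lt(sh$length_um * sh$width_um, 3 * 0.9)  # area decays
  expect_true(all(sh$length_um >= sh$width_um))
})

test_that("rendering produces a background field and resolvable cells", {
  tr <- constant_trace(37, 10)
  cfg <- movie_config(tr, 5, dim_px = c(120, 200), seed = 1, noise_sd = 0.02)
  empty <- cell_population(1, growth_model(), frame_um(cfg), temp_C = 37,
                           col_spacing_um = 10, lane_spacing_um = 6)[0, ]
  class(empty) <- c("cell_population", "data.frame")
  set.seed(1)
  fr0 <- render_frame(empty, cfg)
  expect_equal(mean(fr0$image), 0.5, tolerance = 0.01)
  expect_equal(sd(fr0$image), 0.02, tolerance = 0.1)
  # one noiseless cell is segmentable and sized to the ground truth
  cfg0 <- movie_config(tr, 5, dim_px = c(120, 200), seed = 1, noise_sd = 0)
  one <- cell_population(1, growth_model(), frame_um(cfg0), temp_C = 37,
                         col_spacing_um = 10, lane_spacing_um = 6)
  one$x_um <- 11; one$y_um <- 6.6; one$length_um <- 4; one$angle <- 0
  fr <- render_frame(one, cfg0)
  lab <- segment_frame(fr$image)
  expect_identical(max(lab), 1L)
  meas <- measure_labels(lab, pixel_size_um = cfg0$pixel_size_um)
  expect_equal(meas$length_um, 4, tolerance = cfg0$pixel_size_um / 4)
})

test_that("global drift shows up as the cross-correlation peak", {
  tr <- constant_trace(37, 10)
  cfg <- movie_config(tr, 5, dim_px = c(150, 260), seed = 3, noise_sd = 0.01)
  set.seed(3)
  cells <- cell_population(3, growth_model(), frame_um(cfg), temp_C = 37,
                           col_spacing_um = 8, lane_spacing_um = 5)
  set.seed(3)
  f1 <- render_frame(cells, cfg, drift_px = c(0, 0))$image
  f2 <- render_frame(cells, cfg, drift_px = c(4, -3))$image
  sh <- thermocell:::.xcorr_shift(f2 - mean(f2), f1 - mean(f1))
  expect_equal(sh[1:2], c(4, -3))
})

test_that("movies are reproducible and internally consistent", {
  mv1 <- small_movie(n_cells = 6, duration_min = 10, seed = 8)
  mv2 <- small_movie(n_cells = 6, duration_min = 10, seed = 8)
  expect_identical(mv1$truth, mv2$truth)
  expect_identical(mv1$frames[[5]], mv2$frames[[5]])
  # population size never decreases for wildtype movies
  counts <- as.integer(table(mv1$truth$frame))
  expect_true(all(diff(counts) >= 0))
  # generator self-consistency: d log L / dt over a division-free stretch
  # equals the recorded instantaneous rate
  tru <- mv1$truth
  ids <- names(which(table(tru$id) >= 8))
  cell <- tru[tru$id == as.integer(ids[1]), ]
  cell <- cell[order(cell$frame), ]
  dlog <- diff(log(cell$length_um)) / (30 / 3600)
  expect_equal(dlog, cell$rate_per_h[-1], tolerance = 1e-9)
})

test_that("movies write and read back as TIFF plus truth table", {
  mv <- small_movie(n_cells = 4, duration_min = 5, seed = 2)
  tif <- withr::local_tempfile(fileext = ".tiff")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_movie(mv, tif, csv)
  stack <- read_stack(tif)
  expect_identical(length(stack), length(mv$frames))
  expect_lt(max(abs(stack[[3]] - mv$frames[[3]])), 1 / 255)  # 8-bit rounding
  truth <- utils::read.csv(csv)
  expect_identical(nrow(truth), nrow(mv$truth))
})

test_that("crowding switches the analyzable flag off", {
  tr <- constant_trace(37, 20)
  cfg <- movie_config(tr, 15, dim_px = c(60, 100), seed = 6, noise_sd = 0,
                      crowding_limit = 0.2)
  m <- growth_model()
  set.seed(6)
  cells <- cell_population(2, m, frame_um(cfg), temp_C = 37,
                           col_spacing_um = 5, lane_spacing_um = 2)
  cells$length_um <- 6
  mv <- simulate_movie(cfg, m, cells)
  fl <- tapply(mv$truth$analyzable, mv$truth$frame, unique)
  expect_true(fl[[1]])
  expect_false(fl[[length(fl)]])
})
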