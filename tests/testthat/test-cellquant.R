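# Quantification pipeline: registration, segmentation, geometry,
# tracking, growth rates.

test_that("registration recovers pure translations exactly", {
  set.seed(20)
  base <- matrix(runif(150 * 200), 150, 200)
  base <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(base), 2)))
  shifts <- rbind(c(0, 0), c(3, 5), c(-4, 2), c(7, -6))
  frames <- lapply(seq_len(nrow(shifts)), function(i)
    thermocell:::.shift_int(base, shifts[i, 1], shifts[i, 2],
                            fill = median(base)))
  reg <- register_stack(frames)
  expect_equal(unname(reg$offsets), shifts)
  # and the aligned frames match the base away from the borders
  expect_equal(reg$frames[[4]][30:120, 30:170], base[30:120, 30:170],
               tolerance = 1e-12)
  # a zero-drift stack reports zero offsets
  reg0 <- register_stack(list(base, base, base))
  expect_true(all(reg0$offsets == 0))
})

test_that("segmentation finds no cells in a blank frame", {
  set.seed(30)
  blank <- matrix(0.5 + rnorm(100 * 120, 0, 0.02), 100, 120)
  expect_identical(max(segment_frame(blank)), 0L)
  expect_identical(max(segment_frame(matrix(0.5, 50, 50))), 0L)
})

test_that("a rendered cell segments with high overlap to its true mask", {
  tr <- constant_trace(37, 10)
  cfg <- movie_config(tr, 5, dim_px = c(90, 140), seed = 1, noise_sd = 0)
  cells <- cell_population(1, growth_model(), frame_um(cfg), temp_C = 37,
                           col_spacing_um = 7, lane_spacing_um = 5)
  cells$x_um <- 7.7; cells$y_um <- 4.95; cells$length_um <- 3.5
  cells$angle <- 0.3
  img <- render_frame(cells, cfg)$image
  lab <- segment_frame(img)
  expect_identical(max(lab), 1L)
  # true spherocylinder mask from the generator geometry
  px <- cfg$pixel_size_um
  r <- cells$width_um / 2 / px; a <- cells$length_um / 2 / px - r
  cx <- cells$x_um / px; cy <- cells$y_um / px
  ux <- cos(cells$angle); uy <- sin(cells$angle)
  co <- expand.grid(row = 1:90, col = 1:140)
  dx <- co$col - cx; dy <- co$row - cy
  s <- pmin(pmax(dx * ux + dy * uy, -a), a)
  truth <- matrix(sqrt((dx - s * ux)^2 + (dy - s * uy)^2) <= r, 90, 140)
  pred <- lab == 1L
  iou <- sum(pred & truth) / sum(pred | truth)
  expect_gte(iou, 0.9)
})

test_that("label counts track the number of cells in a dense frame", {
  mv <- small_movie(n_cells = 10, duration_min = 16, seed = 13,
                    drift = c(0, 0))
  k <- length(mv$frames)
  lab <- segment_frame(mv$frames[[k]])
  n_true <- sum(mv$truth$frame == k)
  expect_lte(abs(max(lab) - n_true) / n_true, 0.05)
})

test_that("subpixel contours enclose the right area", {
  # a disc of radius 15 px
  m <- matrix(0L, 64, 64)
  co <- expand.grid(r = 1:64, c = 1:64)
  inside <- (co$r - 32)^2 + (co$c - 30)^2 <= 15^2
  m[cbind(co$r[inside], co$c[inside])] <- 1L
  ct <- extract_contour(m, 1L)
  expect_equal(contour_area(ct), pi * 225, tolerance = 0.02)
  expect_error(extract_contour(m, 7L), "not present")
  one <- matrix(0L, 10, 10); one[5, 5] <- 1L
  expect_error(extract_contour(one, 1L), "degenerate")
  # synthetic spherocylinder: contour area vs analytic area
  tr <- constant_trace(37, 10)
  cfg <- movie_config(tr, 5, dim_px = c(90, 140), seed = 1, noise_sd = 0)
  cells <- cell_population(1, growth_model(), frame_um(cfg), temp_C = 37,
                           col_spacing_um = 7, lane_spacing_um = 5)
  cells$x_um <- 7.7; cells$y_um <- 4.95; cells$length_um <- 4; cells$angle <- 0
  lab <- segment_frame(render_frame(cells, cfg)$image)
  ct2 <- extract_contour(lab, 1L)
  # oracle: the generator's own pixel mask of the spherocylinder
  px <- cfg$pixel_size_um
  r <- cells$width_um / 2 / px; a <- cells$length_um / 2 / px - r
  co2 <- expand.grid(row = 1:90, col = 1:140)
  dx <- co2$col - cells$x_um / px; dy <- co2$row - cells$y_um / px
  s <- pmin(pmax(dx, -a), a)
  true_px <- sum(sqrt((dx - s)^2 + dy^2) <= r)
  expect_equal(contour_area(ct2), true_px, tolerance = 0.03)
})

test_that("centerline geometry measures rods, discs and bent rods", {
  # ideal spherocylinder, L = 4 um, w = 1 um at 0.1 um/px, rotated
  ct <- spherocylinder_contour(40, 10, angle = 0.4, center = c(50, 60))
  g <- centerline_and_dims(ct, pixel_size_um = 0.1)
  expect_equal(g$length_um, 4, tolerance = 0.05)
  expect_equal(g$width_um, 1, tolerance = 0.05)
  # circle: aspect ratio ~ 1 (the rounding phenotype's signature)
  th <- seq(0, 2 * pi, length.out = 180)[-1]
  circ <- cbind(row = 20 + 8 * sin(th), col = 30 + 8 * cos(th))
  gc <- centerline_and_dims(circ)
  expect_equal(gc$length_um / gc$width_um, 1, tolerance = 0.1)
  expect_equal(gc$length_um, 16, tolerance = 0.1)
  # bent spherocylinder: midline arc of radius 40 px over 1 radian,
  # half-width 5 px, rounded caps; pole-to-pole length = arc + 2 caps
  phi <- seq(-0.5, 0.5, length.out = 100)
  R <- 40
  outer <- cbind(row = (R + 5) * cos(phi), col = (R + 5) * sin(phi))
  inner <- cbind(row = (R - 5) * cos(rev(phi)), col = (R - 5) * sin(rev(phi)))
  cap_at <- function(ang, sign) {
    cx <- R * cos(ang); cy <- R * sin(ang)
    th <- seq(0, pi, length.out = 20)
    # semicircle oriented along the local tangent
    tx <- -sin(ang) * sign; ty <- cos(ang) * sign
    nx <- cos(ang); ny <- sin(ang)
    cbind(row = cx + 5 * (cos(th) * nx + sin(th) * tx),
          col = cy + 5 * (cos(th) * ny + sin(th) * ty))
  }
  bent <- rbind(outer, cap_at(0.5, 1), inner, cap_at(-0.5, -1))
  gb <- centerline_and_dims(bent)
  expect_equal(gb$length_um, R * 1 + 10, tolerance = 0.05)  # arc + 2 caps
  expect_equal(gb$width_um, 10, tolerance = 0.1)
})

test_that("tracking follows static and dividing cells", {
  # two distant static cells: two full tracks, no crossovers
  m <- matrix(0L, 60, 80)
  m[20:24, 10:24] <- 1L
  m[45:49, 50:64] <- 2L
  stack <- list(m, m, m, m)
  trk <- track_cells(stack)
  expect_identical(nrow(trk$tracks), 2L)
  expect_true(all(trk$tracks$start_frame == 1L))
  expect_true(all(trk$tracks$end_frame == 4L))
  expect_identical(nrow(trk$divisions), 0L)
  # centroids never jump between the two sites
  for (t in 1:2) {
    rec <- trk$records[trk$records$track == t, ]
    expect_lt(max(rec$row_px) - min(rec$row_px), 1)
  }
})

test_that("growth rates recover exact exponentials and flat series", {
  lam <- 1.98
  frames <- 1:30
  L <- 2 * exp(lam * (frames - 1) * 30 / 3600)
  rec <- data.frame(track = 1L, frame = frames, label = 1L,
                    row_px = 0, col_px = 0, area_px = 100L,
                    length_um = L, width_um = 0.9)
  lin <- structure(list(tracks = data.frame(track = 1L, parent = NA_integer_,
                                            start_frame = 1L, end_frame = 30L,
                                            fate = "end"),
                        records = rec,
                        divisions = data.frame(track = integer(),
                                               frame = integer(),
                                               daughter1 = integer(),
                                               daughter2 = integer())),
                   class = "lineage_set")
  r <- growth_rates(lin, frame_interval_s = 30)
  expect_equal(r$rate_per_h, rep(lam, nrow(r)), tolerance = 1e-10)
  rec$length_um <- 3
  lin$records <- rec
  r0 <- growth_rates(lin, frame_interval_s = 30)
  expect_true(all(abs(r0$rate_per_h) < 1e-12))
  # too-short track: empty result
  lin$records <- rec[1:4, ]
  expect_identical(nrow(growth_rates(lin, 30)), 0L)
})

test_that("population binning averages series the obvious way", {
  r <- data.frame(track = rep(1:2, each = 10),
                  frame = rep(1:10, 2),
                  time_min = rep(seq(0.5, 5, by = 0.5), 2),
                  rate_per_h = rep(c(1, 3), each = 10))
  pc <- bin_population(r, window_min = 0.5)
  expect_true(all(pc$mean_rate_per_h == 2))
  expect_true(all(abs(pc$sd_rate_per_h - sd(c(1, 3))) < 1e-12))
  expect_true(all(pc$n == 2L))
  same <- r; same$rate_per_h <- 2
  expect_true(all(bin_population(same, 2.5)$sd_rate_per_h == 0))
})

test_that("division histograms bin event times into 5-min windows", {
  lin <- structure(list(
    tracks = data.frame(track = 1:3, parent = NA, start_frame = 1,
                        end_frame = 10, fate = "divided"),
    records = NULL,
    divisions = data.frame(track = 1:3, frame = c(4, 5, 21),
                           daughter1 = 0L, daughter2 = 0L)),
    class = "lineage_set")
  h <- count_divisions(lin, frame_interval_s = 30, window_min = 5)
  expect_equal(h$events[1], 2L)   # frames 4, 5 -> ~2 min
  expect_equal(sum(h$events), 3L)
  none <- lin; none$divisions <- lin$divisions[0, ]
  h0 <- count_divisions(none, 30, total_min = 20)
  expect_true(all(h0$events == 0L))
})

test_that("the pipeline is invariant to a known global drift", {
  mv_still <- small_movie(n_cells = 6, duration_min = 10, seed = 17,
                          drift = c(0, 0))
  mv_drift <- small_movie(n_cells = 6, duration_min = 10, seed = 17,
                          drift = c(0.5, 0.8))
  q1 <- quantify_stack(mv_still)
  q2 <- quantify_stack(mv_drift)
  # recovered offsets follow the applied ramp within a pixel per frame
  n <- length(mv_drift$frames)
  expect_lt(max(abs(q2$offsets[n, ] - mv_drift$drift[n, ])), n * 1)
  expect_lt(mean(abs(q2$offsets[, 1] - mv_drift$drift[, 1])), 1)
  # geometry essentially unchanged by the drift: pair cells by centroid
  # (the stacks are different renderings, so allow subpixel-phase jitter
  # and an occasional segmentation difference near a fresh division)
  k <- n - 3L
  m1 <- q1$measurements[[k]]
  m2 <- q2$measurements[[k]]
  # both quantifications measure on registered frames, so centroids live
  # in the same (drift-free) coordinates
  diffs <- vapply(seq_len(nrow(m1)), function(i) {
    d2 <- (m2$row_px - m1$row_px[i])^2 + (m2$col_px - m1$col_px[i])^2
    j <- which.min(d2)
    if (d2[j] <= 25) abs(m2$length_um[j] - m1$length_um[i]) else NA_real_
  }, numeric(1))
  expect_gt(mean(!is.na(diffs)), 0.8)
  expect_lt(median(diffs, na.rm = TRUE), 0.11)
  # and the recovered rates agree closely
  expect_equal(mean(q2$rates$rate_per_h), mean(q1$rates$rate_per_h),
               tolerance = 0.05)
})

test_that("length trajectories are continuous within tracks", {
  mv <- small_movie(n_cells = 8, duration_min = 15, seed = 23)
  q <- quantify_stack(mv)
  rec <- q$lineages$records
  bad <- 0L; tot <- 0L
  for (tr in split(rec, rec$track)) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    ratio <- tr$length_um[-1] / tr$length_um[-nrow(tr)]
    ratio <- ratio[is.finite(ratio)]
    tot <- tot + length(ratio)
    bad <- bad + sum(ratio < 0.8 | ratio > 1.3)
  }
  expect_lt(bad / tot, 0.02)
})
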