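# Registration, segmentation and subpixel geometry for phase-contrast
# stacks of rod-shaped cells.
#
# Segmentation is classical: background-relative contrast, Gaussian
# smoothing, Otsu threshold, morphological cleaning, and distance-map
# watershed to split touching cells. Contours are extracted at the
# 0.5-level of the smoothed label support, giving subpixel boundaries;
# lengths and widths come from a centerline construction (midline
# between the two contour flanks, extended to the poles).
# Pixel coordinates are 1-based (row, column) throughout.

.shift_int <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  rr <- sr + dr; cc <- sc + dc
  ok_r <- rr >= 1 & rr <= nrow(m); ok_c <- cc >= 1 & cc <= ncol(m)
  out[rr[ok_r], cc[ok_c]] <- m[sr[ok_r], sc[ok_c]]
  out
}

# integer translation of `a` relative to `ref` by FFT cross-correlation;
# returns c(dr, dc, quality) where quality is the normalized peak
.xcorr_shift <- function(a, ref, fref = stats::fft(ref)) {
  nr <- nrow(ref); nc <- ncol(ref)
  cc <- Re(stats::fft(stats::fft(a) * Conj(fref), inverse = TRUE))
  peak <- which.max(cc)
  i0 <- (peak - 1L) %% nr; j0 <- (peak - 1L) %/% nr
  dr <- if (i0 > nr / 2) i0 - nr else i0
  dc <- if (j0 > nc / 2) j0 - nc else j0
  c(dr, dc, max(cc) / (nr * nc * stats::sd(a) * stats::sd(ref)))
}

#' Register an image stack by integer-pixel cross-correlation
#'
#' Translation offsets are estimated by FFT cross-correlation of
#' mean-subtracted images against a template frame that is refreshed
#' every `keyframe_step` frames (a fixed first-frame template
#' decorrelates as cells grow and divide; a fresh template keeps the
#' correlation sharp while the keyframe chain accumulates the absolute
#' drift). Frames are shifted back by the integer offsets, borders
#' filled with the frame median. Frames whose normalized correlation
#' peak falls below `min_peak` reuse the previous offset with a
#' warning.
#'
#' @param frames List of grayscale matrices (>= 2).
#' @param keyframe_step Frames between template refreshes (default 10).
#' @param min_peak Minimum normalized correlation (default 0.1).
#' @return A list with `frames` (aligned) and `offsets` (n x 2 matrix of
#'   the estimated drift of each frame relative to the first, in
#'   pixels, columns `row_px`, `col_px`).
#' @export
register_stack <- function(frames, keyframe_step = 10L, min_peak = 0.1) {
  offsets <- register_offsets(frames, keyframe_step, min_peak)
  out <- frames
  for (k in seq_along(frames))
    if (any(offsets[k, ] != 0))
      out[[k]] <- .shift_int(frames[[k]], -offsets[k, 1L], -offsets[k, 2L],
                             fill = stats::median(frames[[k]]))
  list(frames = out, offsets = offsets)
}

#' @rdname register_stack
#' @export
register_offsets <- function(frames, keyframe_step = 10L, min_peak = 0.1) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  offsets <- matrix(0, length(frames), 2L,
                    dimnames = list(NULL, c("row_px", "col_px")))
  key_idx <- 1L
  key <- frames[[1L]] - mean(frames[[1L]])
  fkey <- stats::fft(key)
  key_off <- c(0, 0)
  for (k in seq_along(frames)[-1L]) {
    a <- frames[[k]] - mean(frames[[k]])
    sh <- .xcorr_shift(a, key, fkey)
    if (!is.finite(sh[3L]) || sh[3L] < min_peak) {
      warning("frame ", k, " could not be registered (peak ",
              signif(sh[3L], 2), "); previous offset reused")
      offsets[k, ] <- offsets[k - 1L, ]
    } else {
      offsets[k, ] <- key_off + sh[1:2]
    }
    if (k - key_idx >= keyframe_step) {
      key_idx <- k
      key <- frames[[k]] - mean(frames[[k]])
      fkey <- stats::fft(key)
      key_off <- offsets[k, ]
    }
  }
  offsets
}

#' Segment one phase-contrast frame
#'
#' Cells are darker than the background: the frame is converted to a
#' background-relative contrast image, smoothed, thresholded by Otsu,
#' cleaned by morphological opening and hole filling, and split into
#' individual cells by watershed on the distance map. A blank frame
#' yields an empty mask, not an error.
#'
#' @param img Grayscale matrix in [0, 1].
#' @param sigma Smoothing sigma in pixels (default 1).
#' @param min_area_px Minimum object area (default 25 px).
#' @param min_contrast Absolute contrast floor below the background
#'   (intensity units, default 0.08): keeps shot noise from segmenting
#'   on blank frames while real cells (contrast ~0.2) pass easily.
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   objects (default 2 px; a flat-ridged rod is never split, while
#'   side-by-side touching cells of ~8 px width still separate).
#' @return Integer label matrix (0 = background, labels 1..n).
#' @export
segment_frame <- function(img, sigma = 1, min_area_px = 25,
                          min_contrast = 0.08, watershed_tolerance = 2) {
  stopifnot(is.matrix(img))
  bg <- stats::median(img)
  inv <- pmax(bg - img, 0)
  if (max(inv) < min_contrast) return(matrix(0L, nrow(img), ncol(img)))
  sm <- EBImage::gblur(EBImage::Image(inv), sigma = sigma)
  th <- EBImage::otsu(sm, range = c(0, max(inv)))
  mask <- sm > max(th, min_contrast)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, shape = "diamond"))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1L)
  lab <- EBImage::imageData(lab)
  # drop undersized fragments, relabel densely
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(matrix(0L, nrow(img), ncol(img)))
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  storage.mode(lab) <- "integer"
  matrix(lab, nrow(img), ncol(img))
}

#' Extract the subpixel contour of one labelled cell
#'
#' The binary support of the label is smoothed with a Gaussian and the
#' closed 0.5-level contour is traced, giving boundary coordinates at
#' subpixel resolution.
#'
#' @param mask Integer label matrix from [segment_frame()].
#' @param label Label to extract (> 0, present in the mask).
#' @param sigma Smoothing sigma in pixels (default 1).
#' @return A closed polygon as a matrix with columns `row`, `col`
#'   (1-based pixel coordinates).
#' @export
extract_contour <- function(mask, label, sigma = 1) {
  stopifnot(is.matrix(mask), label > 0)
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("label ", label, " not present in mask")
  .contour_from_idx(idx, dim(mask), sigma, label)
}

.contour_from_idx <- function(idx, dims, sigma, label) {
  if (nrow(idx) < 4L) stop("degenerate region: label ", label,
                           " has fewer than 4 pixels")
  pad <- ceiling(3 * sigma) + 2L
  r0 <- max(min(idx[, 1L]) - pad, 1L); r1 <- min(max(idx[, 1L]) + pad, dims[1L])
  c0 <- max(min(idx[, 2L]) - pad, 1L); c1 <- min(max(idx[, 2L]) + pad, dims[2L])
  bin <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  bin[cbind(idx[, 1L] - r0 + 1L, idx[, 2L] - c0 + 1L)] <- 1
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(bin),
                                                    sigma = sigma)))
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)), y = seq_len(ncol(sm)),
                                z = sm, levels = 0.5)
  if (length(cl) == 0L) stop("no 0.5-level contour for label ", label)
  best <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1L)))]]
  cbind(row = best$x + r0 - 1, col = best$y + c0 - 1)
}

#' Polygon area by the shoelace formula
#' @param contour Matrix with columns `row`, `col`.
#' @return Enclosed area in px^2.
#' @export
contour_area <- function(contour) {
  x <- contour[, 1L]; y <- contour[, 2L]
  n <- length(x)
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Centerline length and width of a rod-shaped contour
#'
#' The contour is projected onto its principal axis; the two flanks
#' (boundary runs on either side of the axis) are interpolated at a set
#' of axial stations, their midline is smoothed into the centerline and
#' its arc length, extended by the pole radii, gives the cell length.
#' Width is twice the median flank half-distance over the central part
#' of the cell. A round contour degenerates gracefully to
#' length = width = diameter.
#'
#' @param contour Polygon from [extract_contour()].
#' @param pixel_size_um Pixel size; outputs in um (default 1: pixels).
#' @return A list with `length_um`, `width_um`, and `profile` (data
#'   frame: axial station, centerline offset, local width).
#' @export
centerline_and_dims <- function(contour, pixel_size_um = 1) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  if (nrow(contour) < 8L) stop("contour too short for centerline extraction")
  V <- sweep(contour, 2L, colMeans(contour))
  sv <- svd(V)
  u <- sv$v[, 1L]
  s <- as.numeric(V %*% u)
  p <- as.numeric(V %*% sv$v[, 2L])
  r0 <- stats::median(abs(p))
  s_lo <- min(s) + r0; s_hi <- max(s) - r0
  if (s_hi - s_lo < r0 / 2) {
    # round object: caliper dimensions
    d <- (max(s) - min(s) + max(p) - min(p)) / 2
    return(list(length_um = d * pixel_size_um, width_um = d * pixel_size_um,
                profile = NULL))
  }
  ns <- max(7L, min(60L, round((s_hi - s_lo) / max(r0, 1))))
  st <- seq(s_lo, s_hi, length.out = ns)
  upper <- p > 0; lower <- p < 0
  if (sum(upper) < 3L || sum(lower) < 3L)
    stop("cannot identify the two contour flanks")
  up <- stats::approx(s[upper], p[upper], xout = st, rule = 2,
                      ties = mean)$y
  lo <- stats::approx(s[lower], p[lower], xout = st, rule = 2,
                      ties = mean)$y
  ctr <- (up + lo) / 2
  hw <- pmax((up - lo) / 2, 0)
  if (ns >= 8L) ctr <- stats::lowess(st, ctr, f = 1 / 2)$y
  arc <- sum(sqrt(diff(st)^2 + diff(ctr)^2))
  # extend to the poles by the axial extent beyond the flank region (for
  # a spherocylinder this equals the cap radius at each end)
  len <- arc + (s_lo - min(s)) + (max(s) - s_hi)
  central <- st >= s_lo + 0.2 * (s_hi - s_lo) &
             st <= s_hi - 0.2 * (s_hi - s_lo)
  wid <- 2 * stats::median(hw[central])
  list(length_um = len * pixel_size_um, width_um = wid * pixel_size_um,
       profile = data.frame(station_px = st, center_px = ctr,
                            width_px = 2 * hw))
}

#' Measure all labelled cells in a frame
#'
#' Runs [extract_contour()] and [centerline_and_dims()] on every label;
#' labels whose geometry cannot be extracted are returned with NA
#' dimensions rather than failing the frame.
#'
#' @param mask Label matrix from [segment_frame()].
#' @param pixel_size_um Pixel size (um).
#' @return Data frame: `label`, `row_px`, `col_px` (centroid),
#'   `area_px`, `length_um`, `width_um`.
#' @export
measure_labels <- function(mask, pixel_size_um = 1) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0L)
    return(data.frame(label = integer(), row_px = numeric(),
                      col_px = numeric(), area_px = integer(),
                      length_um = numeric(), width_um = numeric()))
  pix <- which(mask > 0)
  by_lab <- split(pix, mask[pix])
  nr <- nrow(mask)
  rows <- lapply(labs, function(lb) {
    lin <- by_lab[[as.character(lb)]]
    idx <- cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
    geom <- tryCatch({
      ct <- .contour_from_idx(idx, dim(mask), 1, lb)
      centerline_and_dims(ct, pixel_size_um)
    }, error = function(e) list(length_um = NA_real_, width_um = NA_real_))
    data.frame(label = lb, row_px = mean(idx[, 1L]), col_px = mean(idx[, 2L]),
               area_px = nrow(idx), length_um = geom$length_um,
               width_um = geom$width_um)
  })
  do.call(rbind, rows)
}
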