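# Lineage tracking, growth-rate estimation and division statistics.
#
# Frame-to-frame assignment is by maximal mask overlap with a
# nearest-centroid fallback inside a displacement gate (cells are
# sessile on the pad). A one-to-two assignment ends the parent track
# and starts two daughters -- a division event. Growth rate is the time
# derivative of log cell length.

#' Track cells across a segmented stack
#'
#' @param label_stack List of label matrices (registered frames), one
#'   per frame, from [segment_frame()].
#' @param measurements List of per-frame data frames from
#'   [measure_labels()] (computed internally when NULL).
#' @param pixel_size_um Pixel size (um), used when measuring.
#' @param gate_px Centroid displacement gate for the fallback
#'   assignment (default 10 px per frame).
#' @param min_overlap_frac Minimum fraction of a region's area that must
#'   overlap its predecessor for an overlap link (default 0.3).
#' @return An object of class `lineage_set`: a list with
#'   \describe{
#'     \item{tracks}{data frame: `track`, `parent`, `start_frame`,
#'       `end_frame`, `fate` (one of "end", "divided", "ambiguous").}
#'     \item{records}{long data frame: `track`, `frame`, `label`,
#'       `row_px`, `col_px`, `area_px`, `length_um`, `width_um`.}
#'     \item{divisions}{data frame: `track`, `frame` (last frame of the
#'       mother), `daughter1`, `daughter2` (track ids).}
#'   }
#' @export
track_cells <- function(label_stack, measurements = NULL, pixel_size_um = 1,
                        gate_px = 10, min_overlap_frac = 0.3) {
  stopifnot(is.list(label_stack), length(label_stack) >= 1L)
  n_frames <- length(label_stack)
  if (is.null(measurements))
    measurements <- lapply(label_stack, measure_labels,
                           pixel_size_um = pixel_size_um)
  tracks <- list()     # per track: parent, start, end, fate
  records <- vector("list", n_frames)
  divisions <- list()
  new_track <- function(parent, frame) {
    id <- length(tracks) + 1L
    tracks[[id]] <<- list(parent = parent, start = frame, end = frame,
                          fate = "end")
    id
  }
  m1 <- measurements[[1L]]
  active <- integer(0)  # label -> track id, for current frame
  if (nrow(m1) > 0L) {
    active <- vapply(seq_len(nrow(m1)), function(i) new_track(NA_integer_, 1L),
                     integer(1L))
    names(active) <- as.character(m1$label)
    records[[1L]] <- cbind(track = unname(active), frame = 1L, m1)
  }
  for (k in seq_len(n_frames - 1L)) {
    prev <- label_stack[[k]]; cur <- label_stack[[k + 1L]]
    mprev <- measurements[[k]]; mcur <- measurements[[k + 1L]]
    nxt <- integer(0)
    if (nrow(mcur) > 0L) {
      # overlap counts between prev and cur labels
      both <- which(prev > 0L & cur > 0L)
      link <- integer(nrow(mcur)); names(link) <- as.character(mcur$label)
      if (length(both) > 0L) {
        key <- paste(prev[both], cur[both])
        cnt <- table(key)
        parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
        ov <- data.frame(from = as.integer(parts[, 1L]),
                         to = as.integer(parts[, 2L]),
                         n = as.integer(cnt))
        for (i in seq_len(nrow(mcur))) {
          cand <- ov[ov$to == mcur$label[i], ]
          if (nrow(cand) > 0L) {
            b <- cand[which.max(cand$n), ]
            if (b$n >= min_overlap_frac * mcur$area_px[i])
              link[i] <- b$from
          }
        }
      }
      # fallback: nearest previous centroid within the gate
      unlinked <- which(link == 0L)
      if (length(unlinked) > 0L && nrow(mprev) > 0L) {
        taken <- unique(link[link > 0L])
        for (i in unlinked) {
          d2 <- (mprev$row_px - mcur$row_px[i])^2 +
                (mprev$col_px - mcur$col_px[i])^2
          j <- which.min(d2)
          if (d2[j] <= gate_px^2 && !(mprev$label[j] %in% taken))
            link[i] <- mprev$label[j]
        }
      }
      # resolve links per previous label
      nxt <- integer(nrow(mcur)); names(nxt) <- as.character(mcur$label)
      for (pl in unique(link[link > 0L])) {
        kids <- which(link == pl)
        tid <- active[as.character(pl)]
        if (is.na(tid)) { for (i in kids) nxt[i] <- new_track(NA_integer_, k + 1L); next }
        if (length(kids) == 1L) {
          nxt[kids] <- tid
          tracks[[tid]]$end <- k + 1L
        } else if (length(kids) == 2L) {
          tracks[[tid]]$fate <- "divided"
          d1 <- new_track(tid, k + 1L); d2 <- new_track(tid, k + 1L)
          nxt[kids[1L]] <- d1; nxt[kids[2L]] <- d2
          divisions[[length(divisions) + 1L]] <-
            data.frame(track = tid, frame = k, daughter1 = d1, daughter2 = d2)
        } else {
          tracks[[tid]]$fate <- "ambiguous"
          for (i in kids) nxt[i] <- new_track(NA_integer_, k + 1L)
        }
      }
      for (i in which(nxt == 0L)) nxt[i] <- new_track(NA_integer_, k + 1L)
      records[[k + 1L]] <- cbind(track = unname(nxt), frame = k + 1L, mcur)
    }
    active <- nxt
  }
  trk <- if (length(tracks) > 0L)
    data.frame(track = seq_along(tracks),
               parent = vapply(tracks, function(t) t$parent, integer(1L)),
               start_frame = vapply(tracks, function(t) t$start, integer(1L)),
               end_frame = vapply(tracks, function(t) t$end, integer(1L)),
               fate = vapply(tracks, function(t) t$fate, character(1L)))
  else data.frame(track = integer(), parent = integer(),
                  start_frame = integer(), end_frame = integer(),
                  fate = character())
  structure(list(
    tracks = trk,
    records = if (length(records) > 0L) do.call(rbind, records) else NULL,
    divisions = if (length(divisions) > 0L) do.call(rbind, divisions)
                else data.frame(track = integer(), frame = integer(),
                                daughter1 = integer(), daughter2 = integer())),
    class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat(sprintf("lineage_set: %d tracks, %d division events, %d records\n",
              nrow(x$tracks), nrow(x$divisions),
              if (is.null(x$records)) 0L else nrow(x$records)))
  invisible(x)
}

#' Growth-rate trajectories from tracked lineages
#'
#' For every track longer than the smoothing window, the log length is
#' smoothed by a centered moving average and differentiated by central
#' differences; rates are in 1/h. Division events terminate tracks, so
#' no sample spans a division. Frames whose frame-to-frame length ratio
#' falls outside `[0.8, 1.3]` (segmentation glitches, merges) are
#' masked.
#'
#' @param lineages A `lineage_set`.
#' @param frame_interval_s Seconds between frames.
#' @param window_frames Moving-average window (default 5 frames).
#' @return Long data frame: `track`, `frame`, `time_min`, `rate_per_h`.
#' @export
growth_rates <- function(lineages, frame_interval_s, window_frames = 5) {
  stopifnot(inherits(lineages, "lineage_set"), frame_interval_s > 0)
  rec <- lineages$records
  if (is.null(rec) || nrow(rec) == 0L)
    return(data.frame(track = integer(), frame = integer(),
                      time_min = numeric(), rate_per_h = numeric()))
  dt_h <- frame_interval_s / 3600
  out <- lapply(split(rec, rec$track), function(tr) {
    tr <- tr[order(tr$frame), ]
    ok <- is.finite(tr$length_um) & tr$length_um > 0
    tr <- tr[ok, ]
    n <- nrow(tr)
    if (n < window_frames + 2L) return(NULL)
    ratio <- c(1, tr$length_um[-1L] / tr$length_um[-n])
    good <- ratio >= 0.8 & ratio <= 1.3
    logl <- log(tr$length_um)
    logl[!good] <- NA
    sm <- as.numeric(stats::filter(logl, rep(1 / window_frames, window_frames),
                                   sides = 2))
    rate <- c(NA, (sm[-(1:2)] - sm[1:(n - 2L)]) / (2 * dt_h), NA)
    keep <- is.finite(rate)
    if (!any(keep)) return(NULL)
    data.frame(track = tr$track[keep], frame = tr$frame[keep],
               time_min = (tr$frame[keep] - 1L) * frame_interval_s / 60,
               rate_per_h = rate[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(track = integer(), frame = integer(),
                      time_min = numeric(), rate_per_h = numeric()))
  rownames(out) <- NULL
  out
}

#' Bin growth-rate trajectories into a population-average curve
#'
#' @param rates Data frame from [growth_rates()] (columns `time_min`,
#'   `rate_per_h`).
#' @param window_min Bin width in minutes (default 2.5).
#' @return Data frame: `time_min` (bin centers), `mean_rate_per_h`,
#'   `sd_rate_per_h`, `n`.
#' @export
bin_population <- function(rates, window_min = 2.5) {
  stopifnot(window_min > 0)
  if (nrow(rates) == 0L)
    return(data.frame(time_min = numeric(), mean_rate_per_h = numeric(),
                      sd_rate_per_h = numeric(), n = integer()))
  b <- floor(rates$time_min / window_min)
  agg <- lapply(split(rates$rate_per_h, b), function(x)
    c(mean(x), stats::sd(x), length(x)))
  m <- do.call(rbind, agg)
  data.frame(time_min = (as.numeric(names(agg)) + 0.5) * window_min,
             mean_rate_per_h = m[, 1L], sd_rate_per_h = m[, 2L],
             n = as.integer(m[, 3L]), row.names = NULL)
}

#' Histogram of division events in time windows
#'
#' @param lineages A `lineage_set`.
#' @param frame_interval_s Seconds between frames.
#' @param window_min Window width (default 5 minutes).
#' @param total_min Histogram span (default: last division; at least one
#'   window).
#' @return Data frame: `time_min` (window centers), `events`.
#' @export
count_divisions <- function(lineages, frame_interval_s, window_min = 5,
                            total_min = NULL) {
  stopifnot(inherits(lineages, "lineage_set"))
  t_min <- (lineages$divisions$frame - 0.5) * frame_interval_s / 60
  if (is.null(total_min))
    total_min <- max(c(t_min, window_min))
  breaks <- seq(0, ceiling(total_min / window_min) * window_min,
                by = window_min)
  counts <- if (length(t_min) > 0L)
    table(cut(t_min, breaks, include.lowest = TRUE))
  else integer(length(breaks) - 1L)
  data.frame(time_min = utils::head(breaks, -1L) + window_min / 2,
             events = as.integer(counts))
}

#' Ground-truth division events of a synthetic movie
#'
#' A division in the generator's truth table is a cell id that stops
#' being listed while two cells naming it as parent appear.
#'
#' @param truth Ground-truth table from [simulate_movie()].
#' @return Data frame: `parent_id`, `frame` (last frame of the mother).
#' @export
truth_divisions <- function(truth) {
  first_frame <- tapply(truth$frame, truth$id, min)
  parent <- truth$parent[match(as.integer(names(first_frame)), truth$id)]
  kids <- !is.na(parent)
  if (!any(kids))
    return(data.frame(parent_id = integer(), frame = integer()))
  ev <- unique(data.frame(parent_id = parent[kids],
                          frame = as.integer(first_frame[kids]) - 1L))
  ev[order(ev$frame, ev$parent_id), ]
}

#' Run the full quantification pipeline on an image stack
#'
#' Registration (optional) -> per-frame segmentation -> subpixel
#' geometry -> lineage tracking -> growth rates -> population curve and
#' division histogram.
#'
#' @param frames List of grayscale matrices (or a `synthetic_movie`,
#'   whose frames are used).
#' @param pixel_size_um Pixel size (um).
#' @param frame_interval_s Seconds between frames.
#' @param register Estimate and undo stage drift first (default TRUE).
#' @param window_frames Growth-rate smoothing window (default 5).
#' @param bin_min Population-curve bin width, minutes (default 2.5).
#' @param ... Passed to [segment_frame()].
#' @return A list of class `quantification`: `labels`, `measurements`,
#'   `lineages`, `rates`, `curve`, `divisions`, `offsets`.
#' @export
quantify_stack <- function(frames, pixel_size_um, frame_interval_s,
                           register = TRUE, window_frames = 5,
                           bin_min = 2.5, ...) {
  if (inherits(frames, "synthetic_movie")) {
    pixel_size_um <- frames$config$pixel_size_um
    frame_interval_s <- frames$config$frame_interval_s
    frames <- frames$frames
  }
  offsets <- NULL
  if (register && length(frames) >= 2L)
    offsets <- register_offsets(frames)
  # streamed: shift, segment and measure one frame at a time so that at
  # most one aligned image is alive alongside the input stack
  labels <- vector("list", length(frames))
  meas <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    img <- frames[[k]]
    if (!is.null(offsets) && any(offsets[k, ] != 0))
      img <- .shift_int(img, -offsets[k, 1L], -offsets[k, 2L],
                        fill = stats::median(img))
    labels[[k]] <- segment_frame(img, ...)
    meas[[k]] <- measure_labels(labels[[k]], pixel_size_um = pixel_size_um)
  }
  lineages <- track_cells(labels, measurements = meas,
                          pixel_size_um = pixel_size_um)
  rates <- growth_rates(lineages, frame_interval_s, window_frames)
  curve <- bin_population(rates, bin_min)
  div <- count_divisions(lineages, frame_interval_s)
  structure(list(labels = labels, measurements = meas, lineages = lineages,
                 rates = rates, curve = curve, divisions = div,
                 offsets = offsets),
            class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  nr <- if (is.null(x$rates)) 0L else nrow(x$rates)
  cat(sprintf("quantification: %d frames, %d tracks, %d rate samples, %d divisions\n",
              length(x$labels), nrow(x$lineages$tracks), nr,
              sum(x$divisions$events)))
  if (nr > 0L)
    cat(sprintf("  population mean rate: %.3f 1/h\n", mean(x$rates$rate_per_h)))
  invisible(x)
}
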