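#' Tracker configuration
#'
#' @param max_match_distance_px maximum centroid displacement (pixels) for
#'   a detection to extend an existing track (default 200, i.e. 2 cm at
#'   the 10 px/cm rendering scale — well above any plausible per-frame ant
#'   displacement).
#' @param max_disappeared_frames consecutive frames a track may go
#'   unmatched before it is closed (default 15, half a second at 30 fps).
#' @param min_blob_area_px smallest connected component (pixels) accepted
#'   as an animal by [detect_ants()] (default 5).
#' @param threshold binarization cutoff: pixels strictly darker than this
#'   intensity are foreground (default 0.5 on a `[0, 1]` scale).
#' @return a list of class `tracker_config`.
#' @export
tracker_config <- function(max_match_distance_px = 200,
                           max_disappeared_frames = 15,
                           min_blob_area_px = 5, threshold = 0.5) {
  for (f in c("max_match_distance_px", "max_disappeared_frames",
              "min_blob_area_px", "threshold")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop_config(f, "must be a positive number")
    }
  }
  structure(list(max_match_distance_px = max_match_distance_px,
                 max_disappeared_frames = max_disappeared_frames,
                 min_blob_area_px = min_blob_area_px, threshold = threshold),
            class = "tracker_config")
}

#' Detect animals in a binarized grayscale frame
#'
#' Thresholds a single-channel image (dark animals on a light background),
#' labels connected components, discards components smaller than
#' `min_blob_area_px`, and returns component centroids. Centroids use
#' continuous image coordinates with the origin at the top-left corner of
#' the first pixel (pixel `[i, j]` has its center at `x = j - 0.5`,
#' `y = i - 0.5`), x right, y down.
#'
#' @param frame numeric matrix in `[0, 1]`; rows are image y.
#' @param cfg a [tracker_config()].
#' @return a tibble with columns `x`, `y`, `area_px` (possibly empty).
#' @export
detect_ants <- function(frame, cfg = tracker_config()) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix (single-channel image)", call. = FALSE)
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("detect_ants requires the EBImage package", call. = FALSE)
  }
  fg <- frame < cfg$threshold
  if (!any(fg)) return(tibble(x = double(), y = double(), area_px = integer()))
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labm <- EBImage::imageData(lab)
  idx <- which(labm > 0, arr.ind = TRUE)
  comp <- labm[labm > 0]
  area <- tabulate(comp)
  keep <- which(area >= cfg$min_blob_area_px)
  if (!length(keep)) {
    return(tibble(x = double(), y = double(), area_px = integer()))
  }
  xs <- tapply(idx[, 2] - 0.5, comp, mean)   # matrix columns are image x
  ys <- tapply(idx[, 1] - 0.5, comp, mean)
  out <- tibble(x = as.numeric(xs[as.character(keep)]),
                y = as.numeric(ys[as.character(keep)]),
                area_px = area[keep])
  out[order(out$x, out$y), ]
}

#' Create an empty centroid tracker
#'
#' The tracker maintains a registry of tracks, each with a stable integer
#' id, its last known centroid, a disappearance counter and a lifecycle
#' state (`active` or `closed`). See [update_tracks()] for the association
#' rule.
#'
#' @param cfg a [tracker_config()].
#' @return a mutable tracker object (environment) of class
#'   `centroid_tracker`.
#' @export
centroid_tracker <- function(cfg = tracker_config()) {
  tr <- new.env(parent = emptyenv())
  tr$cfg <- cfg
  tr$next_id <- 1L
  tr$tracks <- list()   # id -> list(id, points (frame,x,y rows), disappeared, state)
  tr$last_frame <- NA_integer_
  class(tr) <- "centroid_tracker"
  tr
}

#' Advance the tracker by one frame of detections
#'
#' Associates detections to active tracks greedily by ascending pairwise
#' Euclidean distance: the globally closest (track, detection) pair is
#' linked first, then the next closest among the unassigned, and so on;
#' pairs farther than `max_match_distance_px` are rejected. Ties in
#' distance resolve to the lowest track id, so the update is fully
#' deterministic. Unmatched detections register new tracks; tracks
#' unmatched for more than `max_disappeared_frames` consecutive frames are
#' closed and never reused (a later nearby detection starts a fresh id).
#'
#' @param tracker a [centroid_tracker()], modified in place.
#' @param frame_index 0-based frame number; must exceed the previous one.
#' @param detections data frame with columns `x`, `y` (pixels); may be
#'   empty.
#' @return the tracker, invisibly.
#' @export
update_tracks <- function(tracker, frame_index, detections) {
  stopifnot(inherits(tracker, "centroid_tracker"))
  cfg <- tracker$cfg
  det <- as.data.frame(detections)[, c("x", "y"), drop = FALSE]
  if (nrow(det) && (anyNA(det$x) || anyNA(det$y))) {
    stop("detections contain NA coordinates", call. = FALSE)
  }
  if (!is.na(tracker$last_frame) && frame_index <= tracker$last_frame) {
    stop("frame_index must increase between updates", call. = FALSE)
  }
  tracker$last_frame <- as.integer(frame_index)

  active_ids <- names(tracker$tracks)[vapply(tracker$tracks, function(t)
    t$state == "active", TRUE)]
  active_ids <- active_ids[order(as.integer(active_ids))]
  matched_det <- rep(FALSE, nrow(det))
  matched_trk <- setNames(rep(FALSE, length(active_ids)), active_ids)

  if (length(active_ids) && nrow(det)) {
    last <- t(vapply(tracker$tracks[active_ids], function(t) {
      p <- t$points[[length(t$points)]]; c(p[2], p[3])
    }, c(0, 0)))
    dmat <- outer(last[, 1], det$x, "-")^2 + outer(last[, 2], det$y, "-")^2
    # Greedy: ascending distance; ties broken by lowest track id then
    # detection order (row-major scan of the ordered index list).
    ord <- order(dmat)   # column-major; rows already sorted by id
    lim2 <- cfg$max_match_distance_px^2
    for (k in ord) {
      if (dmat[k] > lim2) break
      i <- (k - 1) %% nrow(dmat) + 1   # track row
      j <- (k - 1) %/% nrow(dmat) + 1  # detection col
      if (matched_trk[i] || matched_det[j]) next
      matched_trk[i] <- TRUE
      matched_det[j] <- TRUE
      id <- active_ids[i]
      tr <- tracker$tracks[[id]]
      tr$points[[length(tr$points) + 1L]] <- c(frame_index, det$x[j], det$y[j])
      tr$disappeared <- 0L
      tracker$tracks[[id]] <- tr
    }
  }

  # Unmatched active tracks age; beyond the limit they are closed.
  for (i in seq_along(active_ids)) {
    if (matched_trk[i]) next
    id <- active_ids[i]
    tr <- tracker$tracks[[id]]
    tr$disappeared <- tr$disappeared + 1L
    if (tr$disappeared > cfg$max_disappeared_frames) tr$state <- "closed"
    tracker$tracks[[id]] <- tr
  }

  # Unmatched detections register new tracks.
  for (j in which(!matched_det)) {
    id <- as.character(tracker$next_id)
    tracker$tracks[[id]] <- list(
      id = tracker$next_id,
      points = list(c(frame_index, det$x[j], det$y[j])),
      disappeared = 0L, state = "active")
    tracker$next_id <- tracker$next_id + 1L
  }
  invisible(tracker)
}

#' Run the centroid tracker over a detection stream
#'
#' @param detections tibble with columns `frame`, `x`, `y`; frames are
#'   processed in increasing order (frames with no detections still age
#'   the disappearance counters).
#' @param cfg a [tracker_config()].
#' @param frames optional full frame range (0-based integer vector); by
#'   default `min(frame)..max(frame)` so gaps count as empty frames.
#' @return a tibble of tracks: `track_id`, `frame`, `x`, `y`, `state`.
#' @export
track_detections <- function(detections, cfg = tracker_config(),
                             frames = NULL) {
  detections <- as_tibble(detections)
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  tracker <- centroid_tracker(cfg)
  if (is.null(frames)) {
    if (!nrow(detections)) return(tracks_df(tracker))
    frames <- seq.int(min(detections$frame), max(detections$frame))
  }
  split_det <- split(detections, factor(detections$frame, levels = frames))
  for (f in frames) {
    d <- split_det[[as.character(f)]]
    if (is.null(d)) d <- data.frame(x = double(), y = double())
    update_tracks(tracker, f, d)
  }
  tracks_df(tracker)
}

#' Extract the tracker's registry as a tidy table
#'
#' @param tracker a [centroid_tracker()].
#' @return a tibble `track_id`, `frame`, `x`, `y`, `state`, ordered by
#'   track id then frame.
#' @export
tracks_df <- function(tracker) {
  stopifnot(inherits(tracker, "centroid_tracker"))
  if (!length(tracker$tracks)) {
    return(tibble(track_id = integer(), frame = integer(), x = double(),
                  y = double(), state = character()))
  }
  rows <- lapply(tracker$tracks, function(t) {
    m <- do.call(rbind, t$points)
    tibble(track_id = t$id, frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
           state = t$state)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$track_id, out$frame), ]
}
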