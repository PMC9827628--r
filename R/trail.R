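#' Arena calibration
#'
#' Maps pixel tracks into arena coordinates. The arena convention puts the
#' origin at the bottom-left corner, x across the short dimension, y along
#' the long dimension; the trail runs along the vertical centerline
#' `x = arena_w_cm / 2`. Pixel input uses the image convention (origin
#' top-left, y down), so the y axis is flipped.
#'
#' @param px_per_cm pixels per centimetre (> 0).
#' @param arena_w_cm,arena_h_cm arena dimensions (defaults 21.59, 27.94).
#' @param band_half_width_cm half-width of the trail band (default 0.5).
#' @param droplet_spacing_cm spacing of the trail droplets along the
#'   centerline (default 4; also the default minimum traversal length for
#'   an event).
#' @return a list of class `arena_calibration`.
#' @export
arena_calibration <- function(px_per_cm, arena_w_cm = 21.59,
                              arena_h_cm = 27.94, band_half_width_cm = 0.5,
                              droplet_spacing_cm = 4) {
  if (px_per_cm <= 0) stop_config("px_per_cm", "must be > 0")
  if (band_half_width_cm <= 0 || band_half_width_cm > arena_w_cm / 2) {
    stop_config("band_half_width_cm", "must be positive and within the arena")
  }
  structure(list(px_per_cm = px_per_cm, arena_w_cm = arena_w_cm,
                 arena_h_cm = arena_h_cm,
                 band_half_width_cm = band_half_width_cm,
                 droplet_spacing_cm = droplet_spacing_cm),
            class = "arena_calibration")
}

#' Convert pixel tracks to arena centimetres
#'
#' @param tracks tibble with columns `track_id`, `frame`, `x`, `y`
#'   (pixels, image convention).
#' @param cal an [arena_calibration()].
#' @param tol_frac warn when points map outside the arena by more than
#'   this fraction of a dimension (default 0.05).
#' @return a tibble `track_id`, `frame`, `x_cm`, `y_cm`.
#' @export
calibrate_tracks <- function(tracks, cal, tol_frac = 0.05) {
  stopifnot(inherits(cal, "arena_calibration"))
  tracks <- as_tibble(tracks)
  out <- tibble(track_id = tracks$track_id, frame = tracks$frame,
                x_cm = tracks$x / cal$px_per_cm,
                y_cm = cal$arena_h_cm - tracks$y / cal$px_per_cm)
  over_x <- out$x_cm < -tol_frac * cal$arena_w_cm |
    out$x_cm > (1 + tol_frac) * cal$arena_w_cm
  over_y <- out$y_cm < -tol_frac * cal$arena_h_cm |
    out$y_cm > (1 + tol_frac) * cal$arena_h_cm
  if (any(over_x | over_y)) {
    warning(sum(over_x | over_y),
            " point(s) map outside the arena by more than ",
            tol_frac * 100, "% of a dimension; check the calibration",
            call. = FALSE)
  }
  out
}

#' Detect trail-following events along the arena centerline
#'
#' Segments each track into maximal runs of consecutive samples whose
#' cross-trail coordinate `|x - w/2|` stays within the trail band. A run
#' counts as a trail-following event only if its net displacement along
#' the trail axis (`|y_end - y_start|`) reaches `min_traversal_cm`;
#' in-band dwelling and perpendicular crossings (which enter and leave the
#' band with little axial progress) are not events. Brief band exits
#' shorter than `gap_tolerance_frames` samples are bridged into the
#' surrounding run (default 0, strict).
#'
#' @param track tibble with columns `track_id`, `frame`, `x_cm`, `y_cm`
#'   for one or more tracks (grouped by `track_id`).
#' @param cal an [arena_calibration()].
#' @param min_traversal_cm minimum net along-axis displacement (default
#'   `cal$droplet_spacing_cm`, one inter-droplet spacing).
#' @param gap_tolerance_frames bridge out-of-band gaps up to this many
#'   samples (default 0).
#' @return a tibble of events: `track_id`, `start_frame`, `end_frame`,
#'   `displacement_cm` (net, signed by travel direction), `n_points`.
#' @export
detect_trail_events <- function(track, cal,
                                min_traversal_cm = cal$droplet_spacing_cm,
                                gap_tolerance_frames = 0) {
  stopifnot(inherits(cal, "arena_calibration"))
  track <- as_tibble(track)
  if (!nrow(track)) {
    return(tibble(track_id = integer(), start_frame = integer(),
                  end_frame = integer(), displacement_cm = double(),
                  n_points = integer()))
  }
  events <- lapply(split(track, track$track_id), function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) < 2L) return(NULL)
    inband <- abs(d$x_cm - cal$arena_w_cm / 2) <= cal$band_half_width_cm
    if (gap_tolerance_frames > 0) {
      r <- rle(inband)
      short_gap <- !r$values & r$lengths <= gap_tolerance_frames
      # Only interior gaps flanked by in-band runs are bridged.
      interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[short_gap & interior] <- TRUE
      inband <- inverse.rle(r)
    }
    r <- rle(inband)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    rows <- lapply(runs, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      disp <- d$y_cm[i1] - d$y_cm[i0]
      tibble(track_id = d$track_id[1L], start_frame = d$frame[i0],
             end_frame = d$frame[i1], displacement_cm = disp,
             n_points = i1 - i0 + 1L)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(events)
  if (!nrow(out)) {
    return(tibble(track_id = integer(), start_frame = integer(),
                  end_frame = integer(), displacement_cm = double(),
                  n_points = integer()))
  }
  out <- out[abs(out$displacement_cm) >= min_traversal_cm, ]
  out[order(out$track_id, out$start_frame), ]
}

#' Occupancy density map over the arena
#'
#' Bins track points into a regular grid over the arena; counts are
#' conserved (their sum equals the number of binned points). An optional
#' Gaussian kernel (in cell units) smooths the map for contour rendering;
#' smoothing redistributes mass and is applied after counting.
#'
#' @param tracks calibrated tracks (`x_cm`, `y_cm`).
#' @param cal an [arena_calibration()].
#' @param nx,ny grid dimensions (defaults 43 x 56, about 0.5 cm cells).
#' @param smooth_sigma Gaussian sd in cells; 0 (default) disables
#'   smoothing.
#' @return a list of class `density_map`: `counts` (ny x nx matrix, row 1
#'   at the arena bottom), `density` (smoothed, same shape), `x_breaks`,
#'   `y_breaks`, `n_points`.
#' @export
density_map <- function(tracks, cal, nx = 43, ny = 56, smooth_sigma = 0) {
  stopifnot(inherits(cal, "arena_calibration"))
  tracks <- as_tibble(tracks)
  x_breaks <- seq(0, cal$arena_w_cm, length.out = nx + 1)
  y_breaks <- seq(0, cal$arena_h_cm, length.out = ny + 1)
  counts <- matrix(0L, ny, nx)
  keep <- tracks$x_cm >= 0 & tracks$x_cm <= cal$arena_w_cm &
    tracks$y_cm >= 0 & tracks$y_cm <= cal$arena_h_cm
  if (any(keep)) {
    ix <- pmin(nx, 1L + floor(tracks$x_cm[keep] / cal$arena_w_cm * nx))
    iy <- pmin(ny, 1L + floor(tracks$y_cm[keep] / cal$arena_h_cm * ny))
    tab <- table(factor(iy, levels = 1:ny), factor(ix, levels = 1:nx))
    counts <- matrix(as.integer(tab), ny, nx)
  }
  density <- counts
  if (smooth_sigma > 0) {
    half <- ceiling(3 * smooth_sigma)
    k1 <- stats::dnorm(seq(-half, half), sd = smooth_sigma)
    k1 <- k1 / sum(k1)
    conv0 <- function(v) {
      # zero-padded 1D convolution
      n <- length(v)
      vp <- c(rep(0, half), v, rep(0, half))
      as.numeric(stats::filter(vp, k1, sides = 2))[half + seq_len(n)]
    }
    smooth_1d <- function(v) {
      # renormalize per source cell so edge clipping loses no mass
      w <- conv0(rep(1, length(v)))
      conv0(v / w)
    }
    density <- apply(counts + 0, 2, smooth_1d)        # along y
    density <- t(apply(density, 1, smooth_1d))        # along x
  }
  structure(list(counts = counts, density = density, x_breaks = x_breaks,
                 y_breaks = y_breaks, n_points = sum(counts)),
            class = "density_map")
}

#' Two-way ANOVA with Tukey comparisons on trail-event counts
#'
#' Fits `count ~ caste * treatment` on per-replicate trail-following event
#' counts and reports the ANOVA table together with Tukey-adjusted
#' pairwise comparisons of the four caste x treatment cells.
#'
#' @param results tibble with columns `replicate_id`, `caste`,
#'   `treatment`, `count` (>= 2 replicates per cell; every cell present).
#' @return a list of class `trail_anova`: `anova` (data frame),
#'   `tukey` (tibble of cell contrasts with adjusted p), `cell_means`,
#'   `degenerate` (TRUE when all counts are identical, leaving F
#'   undefined).
#' @export
trail_anova <- function(results) {
  results <- as_tibble(results)
  need <- c("replicate_id", "caste", "treatment", "count")
  stopifnot(all(need %in% names(results)))
  results$caste <- factor(canonical_caste(results$caste), levels = .castes)
  results$treatment <- factor(results$treatment)
  cells <- dplyr::count(results, .data$caste, .data$treatment, .drop = FALSE)
  if (any(cells$n == 0L)) {
    empty <- cells[cells$n == 0L, ]
    stop("empty caste x treatment cell(s): ",
         paste(paste(empty$caste, empty$treatment, sep = ":"), collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$n < 2L)) {
    stop("every caste x treatment cell needs >= 2 replicates", call. = FALSE)
  }
  degenerate <- var(results$count) == 0
  fit <- aov(count ~ caste * treatment, data = results)
  tab <- as.data.frame(summary(fit)[[1]])
  tukey <- if (degenerate) {
    tibble(contrast = character(), diff = double(), lwr = double(),
           upr = double(), p_adj = double())
  } else {
    results$cell <- interaction(results$caste, results$treatment, sep = ":")
    th <- TukeyHSD(aov(count ~ cell, data = results))$cell
    tibble(contrast = rownames(th), diff = th[, "diff"], lwr = th[, "lwr"],
           upr = th[, "upr"], p_adj = th[, "p adj"])
  }
  cell_means <- dplyr::summarise(
    dplyr::group_by(results, .data$caste, .data$treatment),
    n = dplyr::n(), mean = mean(.data$count), sd = sd(.data$count),
    .groups = "drop")
  structure(list(anova = tab, tukey = tukey, cell_means = cell_means,
                 degenerate = degenerate),
            class = "trail_anova")
}
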