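#' Configuration for the arena trajectory simulator
#'
#' Defaults mirror the trail-following bioassay geometry: a
#' 21.59 x 27.94 cm paper arena recorded at 30 fps for 5 minutes with ten
#' ants, the (optional) odor trail running along the centerline of the
#' long dimension.
#'
#' @param n_ants animals per trial (default 10).
#' @param arena_w_cm,arena_h_cm arena dimensions in cm (defaults 21.59 and
#'   27.94; the trail axis is parallel to the `h` dimension).
#' @param fps frame rate in Hz (default 30).
#' @param duration_s recording length in seconds (default 300).
#' @param step_sd_cm per-frame step scale in cm (default 0.3).
#' @param turn_kappa von Mises concentration of the turning-angle
#'   distribution; larger values give straighter paths (default 4).
#' @param trail_bias restoring-force coefficient pulling the cross-trail
#'   coordinate toward the centerline, per frame in `[0, 1]`; 0 disables
#'   attraction (default 0).
#' @param dropout_prob independent per-ant-per-frame detection dropout
#'   probability (default 0).
#' @param px_per_cm rendering/detection scale (default 10).
#' @param seed integer seed.
#' @return a list of class `arena_sim_config`.
#' @export
arena_sim_config <- function(n_ants = 10, arena_w_cm = 21.59,
                             arena_h_cm = 27.94, fps = 30, duration_s = 300,
                             step_sd_cm = 0.3, turn_kappa = 4,
                             trail_bias = 0, dropout_prob = 0,
                             px_per_cm = 10, seed = 1L) {
  if (px_per_cm <= 0) stop_config("px_per_cm", "must be > 0")
  if (n_ants < 1) stop_config("n_ants", "must be >= 1")
  if (step_sd_cm < 0) stop_config("step_sd_cm", "must be >= 0")
  if (trail_bias < 0 || trail_bias > 1) stop_config("trail_bias", "must be in [0, 1]")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop_config("dropout_prob", "must be in [0, 1)")
  }
  structure(list(n_ants = n_ants, arena_w_cm = arena_w_cm,
                 arena_h_cm = arena_h_cm, fps = fps, duration_s = duration_s,
                 step_sd_cm = step_sd_cm, turn_kappa = turn_kappa,
                 trail_bias = trail_bias, dropout_prob = dropout_prob,
                 px_per_cm = px_per_cm, seed = as.integer(seed)),
            class = "arena_sim_config")
}

# von Mises sampler (Best & Fisher 1979 rejection method), mean 0.
rvonmises0 <- function(n, kappa) {
  if (kappa <= 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  out
}

#' Simulate correlated-random-walk arena trajectories
#'
#' Each ant performs a correlated random walk: headings evolve by von
#' Mises turning increments (concentration `turn_kappa`), step lengths are
#' folded-normal with scale `step_sd_cm`, and walls reflect both position
#' and heading so trajectories never leave the arena. With
#' `trail_bias > 0`, a restoring displacement `-trail_bias * (x - w/2)`
#' pulls the cross-trail coordinate toward the centerline each frame,
#' producing trail-follower behavior; `trail_bias = 0` gives an unbiased
#' walk.
#'
#' Ground-truth identities are retained for tracker validation. The
#' detection stream gives one centroid per ant per frame in pixel
#' coordinates (image convention: origin top-left, y down), minus
#' independent Bernoulli dropout when configured.
#'
#' @param cfg an [arena_sim_config()].
#' @return a list with `truth` (tibble `ant_id`, `frame`, `x_cm`, `y_cm`),
#'   `detections` (tibble `frame`, `x`, `y` in pixels, identity-free) and
#'   `config`.
#' @seealso [render_arena_frames()], [track_detections()]
#' @export
simulate_arena_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "arena_sim_config"))
  withr::with_seed(cfg$seed, {
    n_frames <- round(cfg$fps * cfg$duration_s)
    w <- cfg$arena_w_cm; h <- cfg$arena_h_cm
    truth <- vector("list", cfg$n_ants)
    for (a in seq_len(cfg$n_ants)) {
      x <- numeric(n_frames); y <- numeric(n_frames)
      x[1] <- runif(1, 0.05 * w, 0.95 * w)
      y[1] <- runif(1, 0.05 * h, 0.95 * h)
      theta <- runif(1, -pi, pi)
      if (cfg$step_sd_cm > 0) {
        turns <- rvonmises0(n_frames - 1, cfg$turn_kappa)
        steps <- abs(rnorm(n_frames - 1, 0, cfg$step_sd_cm))
        for (t in seq_len(n_frames - 1)) {
          theta <- theta + turns[t]
          nx <- x[t] + steps[t] * cos(theta)
          ny <- y[t] + steps[t] * sin(theta)
          if (cfg$trail_bias > 0) {
            nx <- nx - cfg$trail_bias * (nx - w / 2)
          }
          # Reflecting walls (repeat in case a step crosses twice).
          while (nx < 0 || nx > w) nx <- ifelse(nx < 0, -nx, 2 * w - nx)
          while (ny < 0 || ny > h) ny <- ifelse(ny < 0, -ny, 2 * h - ny)
          x[t + 1] <- nx; y[t + 1] <- ny
        }
      } else {
        x[] <- x[1]; y[] <- y[1]
      }
      truth[[a]] <- tibble(ant_id = a, frame = seq_len(n_frames) - 1L,
                           x_cm = x, y_cm = y)
    }
    truth <- dplyr::bind_rows(truth)
    det <- truth
    det$x <- det$x_cm * cfg$px_per_cm
    det$y <- (h - det$y_cm) * cfg$px_per_cm   # image convention: y down
    if (cfg$dropout_prob > 0) {
      det <- det[runif(nrow(det)) >= cfg$dropout_prob, ]
    }
    detections <- det[order(det$frame, det$x), c("frame", "x", "y")]
    list(truth = truth, detections = detections, config = cfg)
  })
}

#' Render detection frames as binary images
#'
#' Draws each ant as a black disc on a white background, the way arena
#' videos look after brightness/contrast adjustment, for exercising the
#' image-based detection path.
#'
#' @param sim output of [simulate_arena_tracks()].
#' @param frames integer vector of frame indices to render (0-based).
#' @param radius_px blob radius in pixels (default 3).
#' @return a named list of numeric matrices in `[0, 1]` (1 = white), one
#'   per requested frame; rows are image y (down), columns image x.
#' @export
render_arena_frames <- function(sim, frames, radius_px = 3) {
  cfg <- sim$config
  nr <- ceiling(cfg$arena_h_cm * cfg$px_per_cm)
  nc <- ceiling(cfg$arena_w_cm * cfg$px_per_cm)
  out <- list()
  for (f in frames) {
    img <- matrix(1, nr, nc)
    d <- sim$detections[sim$detections$frame == f, ]
    for (i in seq_len(nrow(d))) {
      # pixel centers at (col - 0.5, row - 0.5) in continuous image coords
      cols <- pmax(1, pmin(nc, round(d$x[i] + 0.5) + seq(-radius_px, radius_px)))
      rows <- pmax(1, pmin(nr, round(d$y[i] + 0.5) + seq(-radius_px, radius_px)))
      for (r in unique(rows)) for (cc in unique(cols)) {
        if ((r - 0.5 - d$y[i])^2 + (cc - 0.5 - d$x[i])^2 <= radius_px^2) {
          img[r, cc] <- 0
        }
      }
    }
    out[[as.character(f)]] <- img
  }
  out
}
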