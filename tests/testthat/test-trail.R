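cal <- arena_calibration(px_per_cm = 10)

test_that("pixel-to-arena calibration scales, flips y, and round-trips", {
  tracks <- tibble::tibble(track_id = 1L, frame = 0:1,
                           x = c(100, 0), y = c(0, 279.4))
  out <- calibrate_tracks(tracks, cal)
  expect_equal(out$x_cm[1], 10)
  expect_equal(out$y_cm[1], 27.94)    # image top maps to arena top (y up)
  expect_equal(out$y_cm[2], 0)
  # round trip cm -> px -> cm
  set.seed(2)
  cm <- tibble::tibble(track_id = 1L, frame = 0:99,
                       x_cm = runif(100, 0, 21.59), y_cm = runif(100, 0, 27.94))
  px <- tibble::tibble(track_id = 1L, frame = cm$frame,
                       x = cm$x_cm * 10, y = (27.94 - cm$y_cm) * 10)
  back <- calibrate_tracks(px, cal)
  expect_equal(back$x_cm, cm$x_cm, tolerance = 1e-9)
  expect_equal(back$y_cm, cm$y_cm, tolerance = 1e-9)
})

test_that("points far outside the arena trigger a calibration warning", {
  tracks <- tibble::tibble(track_id = 1L, frame = 0L, x = -50, y = 0)
  expect_warning(calibrate_tracks(tracks, cal), "calibration")
})

test_that("an end-to-end centerline path is exactly one trail event", {
  tk <- make_track(x_cm = rep(21.59 / 2, 50), y_cm = seq(0, 27.94, length.out = 50))
  ev <- detect_trail_events(tk, cal)
  expect_identical(nrow(ev), 1L)
  expect_equal(abs(ev$displacement_cm), 27.94)
})

test_that("perpendicular crossings are not trail events", {
  tk <- make_track(x_cm = seq(0, 21.59, length.out = 60), y_cm = rep(14, 60))
  expect_identical(nrow(detect_trail_events(tk, cal)), 0L)
})

test_that("re-entries with sufficient axial advance are counted separately", {
  # enter band, advance 6 cm, leave, re-enter, advance 5 cm
  xc <- 21.59 / 2
  x <- c(xc, xc, xc, xc + 5, xc + 5, xc, xc, xc)
  y <- c(2, 5, 8, 8.5, 9, 10, 12, 15)
  ev <- detect_trail_events(make_track(x, y), cal)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$displacement_cm, c(6, 5))
})

test_that("short in-band dwelling below the traversal threshold is ignored", {
  xc <- 21.59 / 2
  tk <- make_track(x_cm = rep(xc, 10), y_cm = seq(10, 12, length.out = 10))
  expect_identical(nrow(detect_trail_events(tk, cal)), 0L)   # 2 cm < 4 cm
  expect_identical(nrow(detect_trail_events(tk, cal, min_traversal_cm = 1)), 1L)
})

test_that("event counts are invariant to mirroring and time reversal", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    x <- pmin(pmax(cumsum(rnorm(n, 0, 1.2)) + 21.59 / 2, 0), 21.59)
    y <- pmin(pmax(cumsum(rnorm(n, 0.4, 1)), 0), 27.94)
    tk <- make_track(x, y)
    base <- nrow(detect_trail_events(tk, cal))
    mirrored <- make_track(21.59 - x, y)
    reversed <- make_track(rev(x), rev(y))
    expect_identical(nrow(detect_trail_events(mirrored, cal)), base)
    expect_identical(nrow(detect_trail_events(reversed, cal)), base)
  }
})

test_that("planted in-band runs are recovered on constructed polylines", {
  xc <- 21.59 / 2
  set.seed(91)
  for (i in 1:50) {
    n_events <- sample(0:3, 1)
    x <- c(); y <- c(); cursor <- 0.5
    for (e in seq_len(n_events)) {
      # out-of-band approach, then an in-band run advancing >= 5 cm
      x <- c(x, xc + 4, xc + runif(4, -0.4, 0.4))
      y <- c(y, cursor, seq(cursor + 0.5, cursor + 5.6, length.out = 4))
      cursor <- cursor + 6
    }
    x <- c(x, xc + 6); y <- c(y, min(cursor, 27.5))   # finish outside band
    ev <- detect_trail_events(make_track(x, y), cal)
    expect_identical(nrow(ev), n_events)
  }
})

test_that("widening the band never shortens total in-band run length", {
  set.seed(12)
  for (i in 1:20) {
    n <- 60
    x <- pmin(pmax(cumsum(rnorm(n, 0, 0.8)) + 21.59 / 2, 0), 21.59)
    y <- seq(0, 25, length.out = n)
    tk <- make_track(x, y)
    narrow <- arena_calibration(10, band_half_width_cm = 0.5)
    wide <- arena_calibration(10, band_half_width_cm = 1.5)
    len <- function(c_) sum(detect_trail_events(tk, c_, min_traversal_cm = 0)$n_points)
    expect_gte(len(wide), len(narrow))
  }
})

test_that("density map conserves counts and matches multinomial expectation", {
  set.seed(5)
  pts <- tibble::tibble(track_id = 1L, frame = seq_len(1e5) - 1L,
                        x_cm = runif(1e5, 0, 21.59), y_cm = runif(1e5, 0, 27.94))
  dm <- density_map(pts, cal, nx = 10, ny = 10)
  expect_identical(sum(dm$counts), 100000L)
  expected <- 1e5 / 100
  sdev <- sqrt(1e5 * (1 / 100) * (99 / 100))
  within4 <- abs(dm$counts - expected) <= 4 * sdev
  expect_gte(mean(within4), 0.99)
  # single point lands fully in one cell
  one <- density_map(tibble::tibble(track_id = 1L, frame = 0L,
                                    x_cm = 1, y_cm = 1), cal, nx = 5, ny = 5)
  expect_identical(sum(one$counts), 1L)
  expect_identical(max(one$counts), 1L)
  # empty input gives an all-zero map
  empty <- density_map(pts[0, ], cal, nx = 5, ny = 5)
  expect_true(all(empty$counts == 0))
  # smoothing preserves total mass
  sm <- density_map(pts, cal, nx = 10, ny = 10, smooth_sigma = 1)
  expect_equal(sum(sm$density), sum(sm$counts), tolerance = 1e-6)
})

test_that("trail attraction raises event counts over the unbiased walk", {
  count_events <- function(bias, seed) {
    cfg <- arena_sim_config(n_ants = 1, duration_s = 60, trail_bias = bias,
                            step_sd_cm = 0.4, seed = seed)
    sim <- simulate_arena_tracks(cfg)
    tracks <- track_detections(sim$detections)
    nrow(detect_trail_events(calibrate_tracks(tracks, cal), cal))
  }
  biased <- vapply(1:20, function(s) count_events(0.25, s), 0L)
  unbiased <- vapply(1:20, function(s) count_events(0, s), 0L)
  expect_gt(mean(biased), mean(unbiased))
})

test_that("two-way trail ANOVA detects a planted treatment effect in one caste", {
  set.seed(77)
  hits <- 0L
  for (i in 1:40) {
    results <- expand.grid(replicate_id = 1:7, caste = c("minor", "major"),
                           treatment = c("solvent", "pheromone"),
                           stringsAsFactors = FALSE)
    mu <- ifelse(results$caste == "minor" & results$treatment == "pheromone", 9, 3)
    results$count <- round(pmax(rnorm(nrow(results), mu, 2), 0))
    ta <- trail_anova(results)
    row <- ta$tukey[ta$tukey$contrast %in%
                      c("minor:pheromone-minor:solvent",
                        "minor:solvent-minor:pheromone"), ]
    if (nrow(row) && row$p_adj < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.8)
})

test_that("degenerate and malformed trail designs are flagged", {
  results <- expand.grid(replicate_id = 1:3, caste = c("minor", "major"),
                         treatment = c("solvent", "pheromone"),
                         stringsAsFactors = FALSE)
  results$count <- 5
  ta <- trail_anova(results)
  expect_true(ta$degenerate)
  expect_identical(nrow(ta$tukey), 0L)
  expect_error(trail_anova(results[results$caste == "minor", ]), "empty")
})
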