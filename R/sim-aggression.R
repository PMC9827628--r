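#' Configuration for the aggression-trial simulator
#'
#' @param n_trials trials to generate (default 10).
#' @param n_frames frames per trial (default 5401: a 3-minute recording at
#'   30 fps with both endpoints captured).
#' @param p_aggr either a single per-frame aggression probability (frames
#'   iid Bernoulli) or a length-2 vector `c(p01, p10)` of 2-state Markov
#'   transition rates (calm -> aggressive, aggressive -> calm), giving
#'   bout structure with stationary aggressive fraction
#'   `p01 / (p01 + p10)`.
#' @param p_severe per-trial probability that a severe event
#'   (dismemberment) occurs; severe-event frames are drawn uniformly from
#'   the trial's aggressive frames, so severe events only occur in frames
#'   scored 1.
#' @param p_death per-trial probability of a death event, drawn the same
#'   way (default 0).
#' @param seed integer seed.
#' @return a list of class `aggression_sim_config`.
#' @export
aggression_sim_config <- function(n_trials = 10, n_frames = 5401,
                                  p_aggr = 0.3, p_severe = 0, p_death = 0,
                                  seed = 1L) {
  if (n_trials < 1) stop_config("n_trials", "must be >= 1")
  if (n_frames < 1) stop_config("n_frames", "must be >= 1")
  if (!length(p_aggr) %in% 1:2 || any(p_aggr < 0) || any(p_aggr > 1)) {
    stop_config("p_aggr", "probabilities must lie in [0, 1]")
  }
  for (f in c("p_severe", "p_death")) {
    v <- get(f)
    if (v < 0 || v > 1) stop_config(f, "must lie in [0, 1]")
  }
  structure(list(n_trials = n_trials, n_frames = n_frames, p_aggr = p_aggr,
                 p_severe = p_severe, p_death = p_death,
                 seed = as.integer(seed)),
            class = "aggression_sim_config")
}

#' Simulate binary per-frame aggression trials
#'
#' Generates frame-wise binary aggression scores, either iid Bernoulli or
#' as a two-state Markov chain started from its stationary law, plus
#' optional rare severe-event times (dismemberment, death) placed inside
#' aggressive frames.
#'
#' @param cfg an [aggression_sim_config()].
#' @param pairing,relation metadata labels attached to every trial
#'   (defaults `"minor_v_minor"`, `"non_nestmate"`).
#' @return a list of trials; each trial is a list with `trial_id`,
#'   `pairing`, `relation`, `scores` (integer 0/1 vector of length
#'   `n_frames`), `dismemberment_frames`, `death_frames` (0-based).
#' @export
simulate_aggression_trials <- function(cfg, pairing = "minor_v_minor",
                                       relation = "non_nestmate") {
  stopifnot(inherits(cfg, "aggression_sim_config"))
  withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_trials), function(i) {
      n <- cfg$n_frames
      if (length(cfg$p_aggr) == 1L) {
        scores <- rbinom(n, 1L, cfg$p_aggr)
      } else {
        p01 <- cfg$p_aggr[1]; p10 <- cfg$p_aggr[2]
        pi1 <- if (p01 + p10 > 0) p01 / (p01 + p10) else 0
        scores <- integer(n)
        scores[1] <- rbinom(1, 1, pi1)
        u <- runif(n - 1)
        for (t in seq_len(n - 1)) {
          scores[t + 1] <- if (scores[t] == 1L) as.integer(u[t] >= p10)
                           else as.integer(u[t] < p01)
        }
      }
      aggr_frames <- which(scores == 1L) - 1L
      draw_event <- function(p) {
        if (length(aggr_frames) && runif(1) < p) sample(aggr_frames, 1L)
        else integer(0)
      }
      list(trial_id = sprintf("%s_%s_%02d", pairing, relation, i),
           pairing = pairing, relation = relation, scores = scores,
           dismemberment_frames = draw_event(cfg$p_severe),
           death_frames = draw_event(cfg$p_death))
    })
  })
}

#' Simulate a full aggression study design
#'
#' Emulates the pairing x relation design of the non-nestmate recognition
#' bioassay: three pairings (minor vs minor, minor vs major, major vs
#' major), each run against nestmates and non-nestmates. Nestmate trials
#' show near-zero aggression; non-nestmate trials show sustained
#' aggression, with pairings involving majors both more likely to produce
#' dismemberment/death and — for the mixed pairing, where the major
#' rapidly overwhelms the smaller minor — shorter fights.
#'
#' @param n_per_group trials per (pairing, relation) cell (default 10;
#'   the mixed non-nestmate cell gets one extra trial, mirroring the
#'   10-11 design).
#' @param seed integer seed.
#' @return a flat list of trials (see [simulate_aggression_trials()]).
#' @export
simulate_aggression_study <- function(n_per_group = 10, seed = 1L) {
  design <- tibble(
    pairing = rep(c("minor_v_minor", "minor_v_major", "major_v_major"),
                  each = 2),
    relation = rep(c("nestmate", "non_nestmate"), 3),
    # Markov rates: sustained bouts for non-nestmates, rare flickers for
    # nestmates; the mixed pairing ends faster (larger exit rate).
    p01 = c(0.0005, 0.010, 0.0005, 0.010, 0.0005, 0.010),
    p10 = c(0.05, 0.008, 0.05, 0.020, 0.05, 0.008),
    p_severe = c(0, 0, 0, 0.6, 0, 0.55),
    p_death = c(0, 0, 0, 0.5, 0, 0.35),
    n = n_per_group + c(0, 0, 0, 1, 0, 0)
  )
  out <- list()
  for (i in seq_len(nrow(design))) {
    cfg <- aggression_sim_config(
      n_trials = design$n[i], p_aggr = c(design$p01[i], design$p10[i]),
      p_severe = design$p_severe[i], p_death = design$p_death[i],
      seed = seed + i)
    out <- c(out, simulate_aggression_trials(cfg, design$pairing[i],
                                             design$relation[i]))
  }
  out
}
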