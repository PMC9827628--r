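test_that("duration is the 1-frame count over fps, with the 5401-frame convention", {
  expect_identical(duration_from_scores(rep(0, 100)), 0)
  expect_equal(duration_from_scores(c(rep(1, 30), rep(0, 70))), 1.0)
  expect_equal(duration_from_scores(rep(1, 5401)), 5401 / 30)
  expect_error(duration_from_scores(c(0, 1, 2)), "binary")
  expect_error(duration_from_scores(c(0, NA)), "binary")
})

test_that("duration is arrangement-invariant and linear in the count", {
  set.seed(6)
  for (i in 1:20) {
    v <- rbinom(200, 1, 0.4)
    expect_equal(duration_from_scores(v), duration_from_scores(rev(v)))
    expect_equal(duration_from_scores(v), sum(v) / 30)
  }
})

test_that("time course averages trials frame-wise per group", {
  trials <- list(
    list(trial_id = "a", pairing = "p", relation = "nNM", scores = c(1L, 0L, 1L),
         dismemberment_frames = integer(0), death_frames = integer(0)),
    list(trial_id = "b", pairing = "p", relation = "nNM", scores = c(0L, 0L, 1L),
         dismemberment_frames = integer(0), death_frames = integer(0)))
  tc <- time_course(trials)
  expect_equal(tc$proportion, c(0.5, 0, 1))
  # frame-averaged time course equals mean duration over total duration
  summ <- aggression_summary(trials)
  expect_equal(mean(tc$proportion),
               mean(summ$duration_s) / (length(trials[[1]]$scores) / 30))
  trials[[2]]$scores <- c(0L, 1L)
  expect_error(time_course(trials), "equal length")
})

test_that("generator respects degenerate probabilities and the binary contract", {
  z <- simulate_aggression_trials(aggression_sim_config(n_trials = 3,
                                                        n_frames = 50,
                                                        p_aggr = 0, seed = 1))
  expect_true(all(vapply(z, function(t) all(t$scores == 0L), TRUE)))
  expect_true(all(vapply(z, function(t) length(t$dismemberment_frames) == 0L, TRUE)))
  o <- simulate_aggression_trials(aggression_sim_config(n_trials = 3,
                                                        n_frames = 50,
                                                        p_aggr = 1, seed = 1))
  expect_true(all(vapply(o, function(t) all(t$scores == 1L), TRUE)))
  expect_error(aggression_sim_config(p_aggr = 1.2), "p_aggr")
})

test_that("severe events only occur in aggressive frames, reproducibly", {
  cfg <- aggression_sim_config(n_trials = 20, n_frames = 500,
                               p_aggr = c(0.02, 0.03), p_severe = 0.8,
                               p_death = 0.5, seed = 42)
  trials <- simulate_aggression_trials(cfg)
  expect_identical(trials, simulate_aggression_trials(cfg))
  for (tr in trials) {
    for (fr in c(tr$dismemberment_frames, tr$death_frames)) {
      expect_identical(tr$scores[fr + 1L], 1L)
    }
  }
})

test_that("Markov trials hit their stationary aggressive fraction", {
  # rates with stationary probability 0.3
  cfg <- aggression_sim_config(n_trials = 200, n_frames = 400,
                               p_aggr = c(0.03, 0.07), seed = 9)
  trials <- simulate_aggression_trials(cfg)
  frac <- mean(vapply(trials, function(t) mean(t$scores), 0))
  # autocorrelated chains: conservative SE bound via effective sample size
  rho <- 1 - 0.03 - 0.07
  neff <- 200 * 400 * (1 - rho) / (1 + rho)
  se <- sqrt(0.3 * 0.7 / neff)
  expect_lt(abs(frac - 0.3), 3 * se + 0.01)
})

test_that("pooled two-proportion z-tests match the hand formula", {
  summ <- tibble::tibble(
    pairing = rep(c("A", "B"), each = 10),
    any_dismemberment = c(rep(TRUE, 10), rep(FALSE, 10)),
    any_death = FALSE)
  r <- severe_outcome_tests(summ, m = 3)
  expect_equal(r$z, sqrt(20))              # 10/10 vs 0/10, pooled
  expect_true(r$significant)
  expect_equal(r$alpha_adjusted, 0.05 / 3)

  summ2 <- summ
  summ2$any_dismemberment <- rep(c(TRUE, FALSE), 10)
  r2 <- severe_outcome_tests(summ2, m = 3)  # 5/10 vs 5/10
  expect_equal(r2$z, 0)
  expect_false(r2$significant)

  summ3 <- summ
  summ3$any_dismemberment <- FALSE          # 0/10 vs 0/10
  r3 <- severe_outcome_tests(summ3, m = 3)
  expect_true(r3$degenerate)
  expect_false(r3$significant)
})

test_that("swapping the two groups negates z and preserves p", {
  summ <- tibble::tibble(
    pairing = c(rep("A", 10), rep("B", 12)),
    any_dismemberment = c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 9)),
    any_death = FALSE)
  swapped <- summ
  swapped$pairing <- ifelse(summ$pairing == "A", "B", "A")
  a <- severe_outcome_tests(summ)
  b <- severe_outcome_tests(swapped)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
})

test_that("duration ANOVA has power for a planted short-fight pairing", {
  hits <- 0L
  for (i in 1:40) {
    set.seed(1000 + i)
    design <- expand.grid(pairing = c("mvm", "Mvm", "MvM"),
                          relation = c("NM", "nNM"), trial = 1:10,
                          stringsAsFactors = FALSE)
    mu <- ifelse(design$pairing == "Mvm" & design$relation == "nNM", 50, 100)
    summ <- tibble::tibble(pairing = design$pairing, relation = design$relation,
                           duration_s = rnorm(nrow(design), mu, 10))
    da <- duration_anova(summ)
    sides <- strsplit(da$tukey$contrast, "-", fixed = TRUE)
    of_interest <- vapply(sides, function(s) {
      "Mvm:nNM" %in% s && any(s %in% c("mvm:nNM", "MvM:nNM"))
    }, TRUE)
    if (all(da$tukey$p_adj[of_interest] < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})

test_that("label permutation under the null keeps the significant rate near alpha", {
  set.seed(303)
  sig <- 0L; n_sim <- 200
  for (i in seq_len(n_sim)) {
    design <- expand.grid(pairing = c("a", "b"), relation = c("NM", "nNM"),
                          trial = 1:6, stringsAsFactors = FALSE)
    summ <- tibble::tibble(pairing = sample(design$pairing),
                           relation = design$relation,
                           duration_s = rnorm(nrow(design), 100, 20))
    da <- duration_anova(summ)
    p_int <- da$anova[["Pr(>F)"]][3]
    if (!is.na(p_int) && p_int < 0.05) sig <- sig + 1L
  }
  rate <- sig / n_sim
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("identical durations give a degenerate ANOVA; empty cells error", {
  summ <- tibble::tibble(pairing = rep(c("a", "b"), each = 4),
                         relation = rep(c("NM", "nNM"), 4),
                         duration_s = 5)
  expect_true(duration_anova(summ)$degenerate)
  expect_error(duration_anova(summ[summ$pairing == "a", ]), "two pairing levels")
  # a missing factorial cell (both levels present) is named
  expect_error(
    duration_anova(summ[!(summ$pairing == "a" & summ$relation == "NM"), ]),
    "empty")
})
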