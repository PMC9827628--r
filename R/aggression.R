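#' Aggression duration from binary frame scores
#'
#' Each frame of a trial is scored 0 (no aggression) or 1 (aggression);
#' at `fps` frames per second the total aggression duration is the count
#' of 1-frames divided by `fps`. The duration is linear in the count and
#' invariant to how the aggressive frames are arranged.
#'
#' @param scores binary (0/1) vector.
#' @param fps frame rate in Hz (default 30).
#' @return duration in seconds.
#' @examples
#' duration_from_scores(rep(1, 5401))  # 5401/30 ~ 180.03 s
#' @export
duration_from_scores <- function(scores, fps = 30) {
  if (fps <= 0) stop_config("fps", "must be > 0")
  if (anyNA(scores) || !all(scores %in% c(0, 1))) {
    stop("scores must be a binary 0/1 vector", call. = FALSE)
  }
  sum(scores) / fps
}

#' Summarize a set of aggression trials
#'
#' @param trials list of trials as produced by
#'   [simulate_aggression_trials()] (elements `trial_id`, `pairing`,
#'   `relation`, `scores`, `dismemberment_frames`, `death_frames`).
#' @param fps frame rate (default 30).
#' @return a tibble with one row per trial: `trial_id`, `pairing`,
#'   `relation`, `duration_s`, `any_dismemberment`, `any_death`,
#'   `first_dismemberment_s`, `first_death_s`.
#' @export
aggression_summary <- function(trials, fps = 30) {
  rows <- lapply(trials, function(tr) {
    first_s <- function(fr) if (length(fr)) min(fr) / fps else NA_real_
    tibble(trial_id = tr$trial_id, pairing = tr$pairing,
           relation = tr$relation,
           duration_s = duration_from_scores(tr$scores, fps),
           any_dismemberment = length(tr$dismemberment_frames) > 0,
           any_death = length(tr$death_frames) > 0,
           first_dismemberment_s = first_s(tr$dismemberment_frames),
           first_death_s = first_s(tr$death_frames))
  })
  dplyr::bind_rows(rows)
}

#' Per-frame proportion of trials showing aggression
#'
#' @param trials list of trials (equal-length score vectors) belonging to
#'   one or more (pairing, relation) groups.
#' @return a tibble `pairing`, `relation`, `frame` (0-based),
#'   `proportion`.
#' @export
time_course <- function(trials) {
  groups <- split(trials, vapply(trials, function(tr)
    paste(tr$pairing, tr$relation, sep = "\r"), ""))
  out <- lapply(groups, function(g) {
    gl <- vapply(g, function(tr) length(tr$scores), 0L)
    if (length(unique(gl)) != 1L) {
      stop("all score vectors within a group must have equal length",
           call. = FALSE)
    }
    m <- do.call(rbind, lapply(g, function(tr) tr$scores))
    tibble(pairing = g[[1]]$pairing, relation = g[[1]]$relation,
           frame = seq_len(ncol(m)) - 1L, proportion = colMeans(m))
  })
  dplyr::bind_rows(out)
}

#' Two-proportion z-tests on severe outcomes with Bonferroni control
#'
#' Compares the fraction of trials with at least one severe event
#' (dismemberment, or death) between groups with the pooled two-proportion
#' z-test, for every unordered pair of groups, declaring significance at
#' the Bonferroni-corrected level `alpha_family / m`. When both groups
#' have proportion 0 (or both 1), the pooled standard error vanishes and z
#' is undefined: the comparison is reported non-significant and flagged.
#'
#' @param summaries tibble from [aggression_summary()]; groups are defined
#'   by `pairing` (restricted to one `relation` by the caller if desired).
#' @param outcome column to test: `"any_dismemberment"` (default) or
#'   `"any_death"`.
#' @param alpha_family family-wise level (default 0.05).
#' @param m number of comparisons for the Bonferroni divisor (default: the
#'   number of group pairs).
#' @param pooled use the pooled standard error (default `TRUE`; unpooled
#'   available for sensitivity).
#' @return a tibble with one row per group pair: `group1`, `group2`,
#'   `k1`, `n1`, `k2`, `n2`, `z`, `p_value`, `alpha_adjusted`,
#'   `significant`, `degenerate`.
#' @export
severe_outcome_tests <- function(summaries,
                                 outcome = c("any_dismemberment", "any_death"),
                                 alpha_family = 0.05, m = NULL,
                                 pooled = TRUE) {
  outcome <- match.arg(outcome)
  summaries <- as_tibble(summaries)
  per <- dplyr::summarise(dplyr::group_by(summaries, .data$pairing),
                          n = dplyr::n(), k = sum(.data[[outcome]]),
                          .groups = "drop")
  if (nrow(per) < 2L) stop("need at least two groups", call. = FALSE)
  cmb <- utils::combn(nrow(per), 2)
  m <- m %||% ncol(cmb)
  alpha_adj <- alpha_family / m
  rows <- lapply(seq_len(ncol(cmb)), function(ci) {
    i <- cmb[1, ci]; j <- cmb[2, ci]
    k1 <- per$k[i]; n1 <- per$n[i]; k2 <- per$k[j]; n2 <- per$n[j]
    p1 <- k1 / n1; p2 <- k2 / n2
    se <- if (pooled) {
      pp <- (k1 + k2) / (n1 + n2)
      sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    } else {
      sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    }
    degenerate <- se == 0
    z <- if (degenerate) NA_real_ else (p1 - p2) / se
    p <- if (degenerate) NA_real_ else 2 * pnorm(-abs(z))
    tibble(group1 = per$pairing[i], group2 = per$pairing[j],
           k1 = k1, n1 = n1, k2 = k2, n2 = n2, z = z, p_value = p,
           alpha_adjusted = alpha_adj,
           significant = !degenerate && p < alpha_adj,
           degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Two-way ANOVA with Tukey comparisons on aggression durations
#'
#' Fits `duration_s ~ pairing * relation` and reports the ANOVA table and
#' Tukey-adjusted pairwise comparisons of the pairing x relation cells.
#'
#' @param summaries tibble from [aggression_summary()] (>= 2 trials per
#'   cell; every cell present).
#' @return a list of class `aggression_anova` mirroring [trail_anova()]:
#'   `anova`, `tukey`, `cell_means`, `degenerate`.
#' @export
duration_anova <- function(summaries) {
  s <- as_tibble(summaries)
  stopifnot(all(c("pairing", "relation", "duration_s") %in% names(s)))
  s$pairing <- factor(s$pairing)
  s$relation <- factor(s$relation)
  if (nlevels(s$pairing) < 2L || nlevels(s$relation) < 2L) {
    stop("need at least two pairing levels and two relation levels ",
         "(a one-level design leaves the factorial cells empty)",
         call. = FALSE)
  }
  cells <- dplyr::count(s, .data$pairing, .data$relation, .drop = FALSE)
  if (any(cells$n == 0L)) {
    empty <- cells[cells$n == 0L, ]
    stop("empty pairing x relation cell(s): ",
         paste(paste(empty$pairing, empty$relation, sep = ":"),
               collapse = ", "), call. = FALSE)
  }
  if (any(cells$n < 2L)) {
    stop("every pairing x relation cell needs >= 2 trials", call. = FALSE)
  }
  degenerate <- var(s$duration_s) == 0
  fit <- aov(duration_s ~ pairing * relation, data = s)
  tab <- as.data.frame(summary(fit)[[1]])
  tukey <- if (degenerate) {
    tibble(contrast = character(), diff = double(), lwr = double(),
           upr = double(), p_adj = double())
  } else {
    s$cell <- interaction(s$pairing, s$relation, sep = ":")
    th <- TukeyHSD(aov(duration_s ~ cell, data = s))$cell
    tibble(contrast = rownames(th), diff = th[, "diff"], lwr = th[, "lwr"],
           upr = th[, "upr"], p_adj = th[, "p adj"])
  }
  cell_means <- dplyr::summarise(
    dplyr::group_by(s, .data$pairing, .data$relation),
    n = dplyr::n(), mean = mean(.data$duration_s), sd = sd(.data$duration_s),
    .groups = "drop")
  structure(list(anova = tab, tukey = tukey, cell_means = cell_means,
                 degenerate = degenerate),
            class = "aggression_anova")
}
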