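# Shared fixture builders (all fixtures are generated in code).

# Minimal valid session: solvent anchors at both ends, odors between.
make_session <- function(solvent_amps = c(1.0, 0.8),
                         solvent_idx = c(0L, 19L),
                         odor_idx = setdiff(seq(0L, max(solvent_idx)), solvent_idx),
                         odor_amps = rep(1, length(odor_idx)),
                         caste = "minor", prep = "p1", qc_pass = TRUE) {
  events <- rbind(
    data.frame(index = solvent_idx, label = "ND96", kind = "solvent",
               amplitude_mV = solvent_amps),
    data.frame(index = odor_idx, label = sprintf("blend_%02d", seq_along(odor_idx)),
               kind = "odor", amplitude_mV = odor_amps)
  )
  eag_session(prep, caste, events,
              qc = list(tetq_mV = if (qc_pass) 2 else 1,
                        solvent_flank_mV = c(1, 1)))
}

# Long-format replicate matrix from per-(blend, caste) generator functions.
make_matrix <- function(n_blends, n_rep, value_fun) {
  rows <- list()
  for (b in seq_len(n_blends)) for (cc in c("minor", "major")) {
    rows[[length(rows) + 1L]] <- data.frame(
      blend_id = b, class = NA_character_, caste = cc,
      preparation_id = sprintf("%s_%d", cc, seq_len(n_rep)),
      value_mV = value_fun(b, cc, n_rep))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("caste_blend_matrix", class(out))
  tibble::as_tibble(out)
}

# Straight polyline track in arena cm.
make_track <- function(x_cm, y_cm, track_id = 1L) {
  tibble::tibble(track_id = track_id, frame = seq_along(x_cm) - 1L,
                 x_cm = x_cm, y_cm = y_cm)
}

# Brute-force Kendall pair labelling, independent of the package path.
brute_pairs <- function(x, y) {
  n <- length(x)
  lab <- character(0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    s <- (x[i] - x[j]) * (y[i] - y[j])
    lab <- c(lab, if (s > 0) "concordant" else if (s < 0) "discordant" else "tied")
  }
  lab
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table.
brute_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
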