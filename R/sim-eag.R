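#' Latent blend-effect table emulating the published caste contrast
#'
#' Returns a fixed per-blend, per-caste table of latent mean normalized EAG
#' responses (mV) used as the default effect structure by
#' [simulate_eag_sessions()]. The table is synthetic: it encodes the
#' qualitative response architecture reported for a 36-blend general-odorant
#' panel screened in minor and major workers, not any measured values.
#' Specifically:
#'
#' * twelve "divergent" blends (ids 3, 8, 11, 14, 16, 17, 18, 20, 21, 24,
#'   34, 35) carry a large minor-over-major contrast; eleven of them are
#'   above-solvent in minors and sub-solvent in majors, while blend 35 is
#'   sub-solvent in both but far lower in majors;
#' * the remaining blends track each other across castes with a small
#'   minor-leaning offset (two blends lean the other way), so most minor
#'   means are above-solvent and majors sit mostly at or below solvent;
#' * the single alkane blend (id 33) sits near the bottom of both rankings,
#'   so its pairwise rank relations are largely conserved between castes.
#'
#' @return a tibble with columns `blend_id`, `class`, `minor`, `major`
#'   (latent means, mV).
#' @seealso [simulate_eag_sessions()], [synthetic_blend_panel()]
#' @export
study_blend_effects <- function() {
  classes <- c(rep("alcohol", 5), rep("aldehyde", 5), rep("amine", 5),
               rep("carboxylic_acid", 4), rep("ester", 7),
               rep("ketone_indole", 4), rep("lactone", 2), "alkane",
               "sulfur", rep("thiazole", 2))
  divergent <- c(3, 8, 11, 14, 16, 17, 18, 20, 21, 24, 34)
  reversed <- c(6, 28)                  # the two blends leaning toward majors
  others <- setdiff(1:36, c(divergent, 35, reversed))
  # Alkane blend 33 takes the lowest latent response in both castes.
  others <- c(setdiff(others, 33), 33)

  minor <- major <- numeric(36)
  minor[divergent] <- seq(0.50, 0.20, length.out = length(divergent))
  major[divergent] <- seq(-0.15, -0.28, length.out = length(divergent))
  minor[35] <- -0.10; major[35] <- -0.45
  minor[others] <- seq(0.46, -0.10, length.out = length(others))
  major[others] <- minor[others] - 0.12
  minor[reversed] <- c(0.15, 0.05)
  major[reversed] <- minor[reversed] + 0.12

  tibble(blend_id = 1:36, class = classes, minor = minor, major = major)
}

#' Configuration for the EAG session simulator
#'
#' @param n_preparations_per_caste preparations (antennae) per caste
#'   (default 25, the panel-screen design size).
#' @param n_blends number of odor blends in the panel (default 36; must be
#'   >= 2).
#' @param caste_effect named numeric, additive mean shift per caste (mV);
#'   default zero for both castes (shifts live in `blend_effects`).
#' @param blend_effects either a numeric vector of length `n_blends`
#'   (shared across castes) or a data frame with columns `blend_id`,
#'   `minor`, `major` (per-caste latent means, mV). Default:
#'   [study_blend_effects()] when `n_blends == 36`, else zeros.
#' @param solvent_mV solvent-alone response at the first stimulus (default
#'   1.0 mV).
#' @param drift_slope linear change of the solvent response per stimulus
#'   index (mV/index; default -0.005, a slow decay emulating antennal
#'   degradation over the session).
#' @param noise_sd replicate noise standard deviation (mV; default 0.25).
#' @param seed integer seed; identical configs and seeds reproduce output
#'   exactly.
#' @return a list of class `eag_sim_config`.
#' @export
eag_sim_config <- function(n_preparations_per_caste = 25, n_blends = 36,
                           caste_effect = c(minor = 0, major = 0),
                           blend_effects = NULL, solvent_mV = 1.0,
                           drift_slope = -0.005, noise_sd = 0.25,
                           seed = 1L) {
  if (n_blends < 2) stop_config("n_blends", "must be >= 2")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (n_preparations_per_caste < 1) {
    stop_config("n_preparations_per_caste", "must be >= 1")
  }
  if (is.null(blend_effects)) {
    blend_effects <- if (n_blends == 36) study_blend_effects() else
      tibble(blend_id = seq_len(n_blends), class = NA_character_,
             minor = rep(0, n_blends), major = rep(0, n_blends))
  } else if (is.numeric(blend_effects)) {
    if (length(blend_effects) != n_blends) {
      stop_config("blend_effects", "length must equal n_blends")
    }
    blend_effects <- tibble(blend_id = seq_len(n_blends), class = NA_character_,
                            minor = blend_effects, major = blend_effects)
  } else {
    blend_effects <- as_tibble(blend_effects)
    if (!all(c("blend_id", "minor", "major") %in% names(blend_effects)) ||
        nrow(blend_effects) != n_blends) {
      stop_config("blend_effects",
                  "need columns blend_id, minor, major with one row per blend")
    }
  }
  if (!all(.castes %in% names(caste_effect))) {
    stop_config("caste_effect", "must be named with 'minor' and 'major'")
  }
  structure(list(n_preparations_per_caste = n_preparations_per_caste,
                 n_blends = n_blends, caste_effect = caste_effect,
                 blend_effects = blend_effects, solvent_mV = solvent_mV,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "eag_sim_config")
}

#' Simulate EAG sessions with linear solvent drift
#'
#' Generates balanced minor/major sessions following the canonical panel
#' ordering: solvent, blends `1..k`, solvent, blends `k+1..n`, solvent
#' (with `k = ceiling(n_blends / 2)`). Solvent amplitudes follow the
#' configured linear drift plus noise; each odor amplitude is the drifting
#' baseline plus its caste and blend effects plus noise. Every session
#' carries a passing TETQ qc record (TETQ at twice the solvent response)
#' so the simulated preparations are valid by construction.
#'
#' Because the generator's drift is exactly linear in stimulus index and
#' the normalization interpolates linearly over the same coordinate,
#' [normalize_session()] recovers the planted effects exactly when
#' `noise_sd = 0`.
#'
#' @param cfg an [eag_sim_config()].
#' @return a list of [eag_session()] objects (minors first), named by
#'   preparation id.
#' @export
simulate_eag_sessions <- function(cfg) {
  stopifnot(inherits(cfg, "eag_sim_config"))
  withr::with_seed(cfg$seed, {
    colonies <- c("C6", "K17", "K19", "K34", "K39", "D601")
    n <- as.integer(cfg$n_blends)
    k <- as.integer(ceiling(n / 2))
    # 0-based event indices: solvent at 0, k+1, n+2; blends in between.
    solvent_idx <- c(0L, k + 1L, n + 2L)
    blend_idx <- setdiff(seq.int(0L, n + 2L), solvent_idx)
    sessions <- list()
    for (caste in .castes) {
      eff <- cfg$blend_effects[[caste]] + cfg$caste_effect[[caste]]
      for (prep in seq_len(cfg$n_preparations_per_caste)) {
        prep_id <- sprintf("%s_%02d", caste, prep)
        drift <- function(i) cfg$solvent_mV + cfg$drift_slope * i
        amp_solvent <- drift(solvent_idx) + rnorm(3, 0, cfg$noise_sd)
        amp_blend <- drift(blend_idx) + eff + rnorm(n, 0, cfg$noise_sd)
        events <- tibble(
          index = c(solvent_idx, blend_idx),
          label = c(rep("ND96", 3), sprintf("blend_%02d", seq_len(n))),
          kind = c(rep("solvent", 3), rep("odor", n)),
          amplitude_mV = c(amp_solvent, amp_blend)
        )
        sessions[[prep_id]] <- eag_session(
          preparation_id = prep_id, caste = caste,
          colony_id = colonies[1L + (prep - 1L) %% length(colonies)],
          events = events,
          qc = list(tetq_mV = 2 * cfg$solvent_mV,
                    solvent_flank_mV = rep(cfg$solvent_mV, 2))
        )
      }
    }
    sessions
  })
}

#' Simulate solvent-normalized dose-response measurements
#'
#' Emulates the two dose-response archetypes seen in caste-comparative
#' EAG work: a sigmoidal (four-parameter logistic) excitatory profile,
#' and a hormetic sub-solvent profile that dips with increasing dose
#' before returning toward baseline at the highest dose.
#'
#' @param profile `"sigmoid"` or `"hormetic"`.
#' @param doses molar concentrations (default `10^seq(-11, -3, by = 2)`,
#'   the five log-spaced panel doses).
#' @param n_replicates preparations per dose (default 5).
#' @param noise_sd replicate noise sd in mV (default 0.05).
#' @param params optional named list overriding the archetype parameters
#'   (`bottom`, `top`, `log10ec50`, `hill` for sigmoid; `dip`, `center`,
#'   `width` for hormetic).
#' @param seed integer seed.
#' @return a tibble with columns `dose_M`, `replicate`, `value_mV`.
#' @export
simulate_dose_response <- function(profile = c("sigmoid", "hormetic"),
                                   doses = 10^seq(-11, -3, by = 2),
                                   n_replicates = 5, noise_sd = 0.05,
                                   params = list(), seed = 1L) {
  profile <- match.arg(profile)
  if (any(doses <= 0)) stop_config("doses", "must be positive")
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  withr::with_seed(seed, {
    x <- log10(doses)
    mu <- if (profile == "sigmoid") {
      p <- utils::modifyList(
        list(bottom = 0, top = 0.6, log10ec50 = -7, hill = 0.8), params)
      p$bottom + (p$top - p$bottom) / (1 + 10^((p$log10ec50 - x) * p$hill))
    } else {
      # Gaussian-shaped dip below solvent, recovering at the extremes.
      p <- utils::modifyList(list(dip = -0.25, center = -7, width = 2.5),
                             params)
      p$dip * exp(-((x - p$center) / p$width)^2)
    }
    tibble(
      dose_M = rep(doses, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(doses)),
      value_mV = rep(mu, each = n_replicates) +
        rnorm(length(doses) * n_replicates, 0, noise_sd)
    )
  })
}
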