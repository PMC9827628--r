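#' Run the end-to-end synthetic study pipeline
#'
#' Executes the selected stages in dependency order on seeded synthetic
#' inputs and aggregates every statistic into a single report:
#'
#' * `eag` — simulate panel sessions, gate and normalize them, then run
#'   the full odor-coding statistics (caste comparison with two-stage FDR,
#'   solvent classification, sign-proportion Fisher test, concordance and
#'   per-class discordance against the blend panel);
#' * `trail` — simulate arena trials for each caste x treatment cell
#'   (treatment modelled as trail attraction on/off), track, calibrate,
#'   count trail-following events, and fit the two-way ANOVA with Tukey
#'   comparisons;
#' * `aggression` — simulate the pairing x relation design, summarize
#'   durations and severe outcomes, and run the duration ANOVA and the
#'   Bonferroni-corrected severe-outcome z-tests.
#'
#' The report is reproducible: identical configs and seeds give identical
#' reports (no timestamps are embedded).
#'
#' @param config a named list; recognized keys: `stages` (subset of
#'   `c("eag", "trail", "aggression")`), `seed` (integer), `alpha`,
#'   `eag` / `trail` / `aggression` (per-stage parameter lists passed to
#'   the respective simulators), `output_dir` (when set, the report JSON
#'   and the resolved config YAML are written there). Unknown keys are
#'   rejected.
#' @return the report, a nested list; invisibly written to
#'   `output_dir/report.json` when requested.
#' @export
run_pipeline <- function(config = list()) {
  known <- c("stages", "seed", "alpha", "eag", "trail", "aggression",
             "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- config$stages %||% c("eag", "trail", "aggression")
  bad <- setdiff(stages, c("eag", "trail", "aggression"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  report <- list(package_version = as.character(utils::packageVersion("antcaste")),
                 seed = seed, alpha = alpha, stages = stages)

  if ("eag" %in% stages) {
    eag_args <- config$eag %||% list()
    cfg <- do.call(eag_sim_config, c(eag_args, list(seed = seed)))
    sessions <- simulate_eag_sessions(cfg)
    normalized <- normalize_sessions(sessions)
    panel <- synthetic_blend_panel()
    mat <- blend_matrix(normalized, panel)
    cmp <- compare_castes(mat, alpha = alpha)
    cls <- classify_vs_solvent(mat, alpha = alpha)
    cls_by_caste <- split(cls$classification, cls$classification$caste)
    fis <- sub_solvent_fisher(cls_by_caste$minor, cls_by_caste$major)
    means <- blend_means(mat)
    mm <- tidyr::pivot_wider(means[, c("blend_id", "caste", "mean_mV")],
                             names_from = "caste", values_from = "mean_mV")
    conc <- concordance_analysis(mm$minor, mm$major, blend_ids = mm$blend_id)
    pcd <- per_class_discordance(conc$pairs, panel)
    report$eag <- list(
      n_sessions = length(sessions),
      n_excluded = length(attr(normalized, "excluded")),
      n_significant_blends = sum(cmp$significant),
      significant_blends = cmp$blend_id[cmp$significant],
      classification_counts = as.data.frame(cls$counts),
      fisher = list(p_value = fis$p_value, odds_ratio = fis$odds_ratio,
                    table = unclass(fis$table)),
      concordance = list(n_pairs = conc$n_pairs,
                         n_concordant = conc$n_concordant,
                         n_discordant = conc$n_discordant,
                         tau_b = conc$tau_b, p_value = conc$p_value),
      per_class_discordance = as.data.frame(pcd)
    )
  }

  if ("trail" %in% stages) {
    trail_args <- config$trail %||% list()
    n_rep <- trail_args$n_replicates %||% 7L
    bias_on <- trail_args$trail_bias %||% 0.25
    duration_s <- trail_args$duration_s %||% 300
    design <- expand.grid(caste = .castes,
                          treatment = c("solvent", "pheromone"),
                          replicate = seq_len(n_rep),
                          stringsAsFactors = FALSE)
    cal <- arena_calibration(px_per_cm = 10)
    counts <- integer(nrow(design))
    for (i in seq_len(nrow(design))) {
      # Only minors respond to the pheromone trail; majors never follow.
      bias <- if (design$treatment[i] == "pheromone" &&
                  design$caste[i] == "minor") bias_on else 0
      cfg <- arena_sim_config(trail_bias = bias, duration_s = duration_s,
                              seed = seed * 1000L + i)
      sim <- simulate_arena_tracks(cfg)
      tracks <- track_detections(sim$detections)
      caltr <- calibrate_tracks(tracks, cal)
      counts[i] <- nrow(detect_trail_events(caltr, cal))
    }
    results <- tibble(replicate_id = design$replicate, caste = design$caste,
                      treatment = design$treatment, count = counts)
    ta <- trail_anova(results)
    report$trail <- list(cell_means = as.data.frame(ta$cell_means),
                         anova = ta$anova, tukey = as.data.frame(ta$tukey))
  }

  if ("aggression" %in% stages) {
    agg_args <- config$aggression %||% list()
    trials <- simulate_aggression_study(
      n_per_group = agg_args$n_per_group %||% 10, seed = seed)
    summ <- aggression_summary(trials)
    nn <- summ[summ$relation == "non_nestmate", ]
    report$aggression <- list(
      n_trials = nrow(summ),
      mean_duration_by_cell = as.data.frame(duration_anova(summ)$cell_means),
      duration_tukey = as.data.frame(duration_anova(summ)$tukey),
      dismemberment_tests = as.data.frame(severe_outcome_tests(nn)),
      death_tests = as.data.frame(
        severe_outcome_tests(nn, outcome = "any_death"))
    )
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    resolved <- config
    resolved$stages <- stages; resolved$seed <- seed; resolved$alpha <- alpha
    yaml::write_yaml(resolved, file.path(config$output_dir, "config.yaml"))
  }
  report
}
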