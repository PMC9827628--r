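#' Preparation-quality gate on the positive-control response
#'
#' Before any panel recording, a preparation is stimulated with solvent,
#' the positive-control compound TETQ (5,6,7,8-tetrahydroquinoline), and
#' solvent again. The preparation is valid only if the TETQ response is
#' strictly greater than `threshold_ratio` times the mean of the flanking
#' solvent responses; a response at or below the threshold marks a
#' defective setup whose recordings are excluded downstream.
#'
#' @param tetq_amplitude TETQ peak response magnitude (mV, non-negative).
#' @param flanking_solvent_amplitudes numeric vector (length >= 1) of the
#'   solvent peak responses bracketing the TETQ pulse.
#' @param threshold_ratio dimensionless gate ratio (default 1.5).
#' @return `TRUE` if the preparation passes the gate, `FALSE` otherwise.
#' @examples
#' qc_gate(1.6, c(1, 1))  # TRUE
#' qc_gate(1.5, c(1, 1))  # FALSE: strict inequality
#' @export
qc_gate <- function(tetq_amplitude, flanking_solvent_amplitudes,
                    threshold_ratio = 1.5) {
  if (length(flanking_solvent_amplitudes) < 1L) {
    stop("at least one flanking solvent amplitude is required", call. = FALSE)
  }
  if (threshold_ratio <= 0) stop_config("threshold_ratio", "must be > 0")
  amps <- c(tetq_amplitude, flanking_solvent_amplitudes)
  if (!all(is.finite(amps)) || any(amps < 0)) {
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  }
  tetq_amplitude > threshold_ratio * mean(flanking_solvent_amplitudes)
}

#' Interpolated solvent baseline at a stimulus position
#'
#' Estimates the solvent-alone response at an arbitrary position in the
#' stimulus sequence by piecewise-linear interpolation, over stimulus
#' index, between the nearest bracketing solvent events. The interpolation
#' coordinate is the stimulus index rather than wall-clock time: stimuli
#' were delivered at approximately regular intervals, so the index is the
#' reliable coordinate. Queries outside the solvent anchor range raise an
#' error; no extrapolation is performed.
#'
#' @param session an [eag_session()].
#' @param at_index stimulus index (0-based) at which to evaluate the
#'   baseline; may be a vector.
#' @return baseline amplitude(s) in mV.
#' @examples
#' s <- eag_session("p1", "minor", data.frame(
#'   index = c(0, 10, 19), label = c("ND96", "blend_10", "ND96"),
#'   kind = c("solvent", "odor", "solvent"), amplitude_mV = c(1.0, 1.3, 0.8)))
#' interpolate_solvent_baseline(s, 10)  # 1.0 + (0.8 - 1.0) * 10/19
#' @export
interpolate_solvent_baseline <- function(session, at_index) {
  stopifnot(inherits(session, "eag_session"))
  sv <- session$events[session$events$kind == "solvent", ]
  if (nrow(sv) < 2L) {
    stop("session needs at least two solvent anchors", call. = FALSE)
  }
  rng <- range(sv$index)
  if (any(at_index < rng[1L] | at_index > rng[2L])) {
    stop(sprintf(
      "index outside the solvent anchor range [%s, %s]; no extrapolation is performed",
      rng[1L], rng[2L]), call. = FALSE)
  }
  approx(sv$index, sv$amplitude_mV, xout = at_index, method = "linear",
         ties = "ordered")$y
}

#' Solvent-normalize the odor responses of a session
#'
#' Converts raw odor peak amplitudes into solvent-relative responses:
#' for every odor event, the interpolated solvent baseline at its stimulus
#' index is subtracted from its amplitude. Positive values are
#' above-solvent (excitatory relative to control); negative values are
#' sub-solvent (suppressed below the control response). Solvent and qc
#' events are excluded from the output. Because the baseline is anchored
#' at the recorded solvent responses, linear drift in antennal sensitivity
#' across the session cancels exactly.
#'
#' @param session an [eag_session()].
#' @param qc_rule list with `threshold_ratio` applied via [qc_gate()] when
#'   the session carries qc measurements; set `waive_qc = TRUE` to process
#'   a session without (or failing) qc, which is flagged in the output.
#' @param waive_qc logical; process despite absent/failed qc (default
#'   `FALSE`).
#' @return a tibble with columns `preparation_id`, `caste`, `colony_id`,
#'   `index`, `label`, `value_mV`, plus an attribute `qc_waived`.
#' @export
normalize_session <- function(session, qc_rule = list(threshold_ratio = 1.5),
                              waive_qc = FALSE) {
  stopifnot(inherits(session, "eag_session"))
  qc_waived <- FALSE
  if (!is.null(session$qc)) {
    ok <- qc_gate(session$qc$tetq_mV, session$qc$solvent_flank_mV,
                  qc_rule$threshold_ratio %||% 1.5)
    if (!ok) {
      if (!waive_qc) {
        stop(sprintf("preparation %s failed the TETQ quality gate; pass waive_qc = TRUE to force",
                     session$preparation_id), call. = FALSE)
      }
      qc_waived <- TRUE
    }
  } else if (!waive_qc) {
    stop(sprintf("preparation %s has no qc record; pass waive_qc = TRUE to process anyway",
                 session$preparation_id), call. = FALSE)
  } else {
    qc_waived <- TRUE
  }
  od <- session$events[session$events$kind == "odor", ]
  baseline <- interpolate_solvent_baseline(session, od$index)
  out <- tibble(
    preparation_id = session$preparation_id,
    caste = session$caste,
    colony_id = session$colony_id,
    index = od$index,
    label = od$label,
    value_mV = od$amplitude_mV - baseline
  )
  attr(out, "qc_waived") <- qc_waived
  out
}

#' Normalize a collection of sessions, applying the quality gate
#'
#' Runs [normalize_session()] over a list of sessions, dropping (and
#' reporting) preparations that fail the TETQ gate.
#'
#' @param sessions list of [eag_session()] objects.
#' @inheritParams normalize_session
#' @return a tibble of normalized responses from all valid sessions; the
#'   attribute `excluded` lists preparation ids that failed the gate.
#' @export
normalize_sessions <- function(sessions, qc_rule = list(threshold_ratio = 1.5)) {
  excluded <- character(0)
  keep <- list()
  for (s in sessions) {
    valid <- !is.null(s$qc) &&
      qc_gate(s$qc$tetq_mV, s$qc$solvent_flank_mV,
              qc_rule$threshold_ratio %||% 1.5)
    if (!valid) {
      excluded <- c(excluded, as.character(s$preparation_id))
      next
    }
    keep[[length(keep) + 1L]] <- normalize_session(s, qc_rule)
  }
  out <- if (length(keep)) dplyr::bind_rows(keep) else
    tibble(preparation_id = character(), caste = character(),
           colony_id = character(), index = integer(), label = character(),
           value_mV = double())
  if (length(excluded)) {
    message("excluded ", length(excluded), " preparation(s) failing the TETQ gate: ",
            paste(excluded, collapse = ", "))
  }
  attr(out, "excluded") <- excluded
  out
}
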