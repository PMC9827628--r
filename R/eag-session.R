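#' Construct an EAG recording session
#'
#' One session is the ordered sequence of stimulus pulses delivered to a
#' single antennal preparation: solvent controls interleaved with odor
#' stimuli, each event carrying the measured peak response amplitude (mV,
#' stored as a positive magnitude). The canonical panel ordering is
#' solvent, odor blends 1-18, solvent, odor blends 19-36, solvent, so that
#' the solvent responses bracket every odor stimulus and drift in antennal
#' sensitivity can be interpolated away.
#'
#' @param preparation_id identifier of the antennal preparation.
#' @param caste worker caste, `"minor"` or `"major"` (case-insensitive).
#' @param events data frame with columns `index` (0-based, unique),
#'   `label`, `kind` (one of `"solvent"`, `"odor"`, `"qc"`) and
#'   `amplitude_mV` (finite). Rows may arrive in any order; they are sorted
#'   by `index`.
#' @param colony_id source colony identifier.
#' @param solvent_label label of the solvent control stimulus (default
#'   `"ND96"`).
#' @param qc optional list with `tetq_mV` (positive-control response) and
#'   `solvent_flank_mV` (numeric vector of the flanking solvent responses),
#'   consumed by [qc_gate()].
#' @return an object of class `eag_session`.
#' @seealso [qc_gate()], [normalize_session()], [simulate_eag_sessions()]
#' @export
eag_session <- function(preparation_id, caste, events, colony_id = NA_character_,
                        solvent_label = "ND96", qc = NULL) {
  caste <- canonical_caste(caste)
  stopifnot(length(caste) == 1L)
  events <- as_tibble(events)
  required <- c("index", "label", "kind", "amplitude_mV")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- events[order(events$index), required]
  if (anyDuplicated(events$index)) {
    stop("event indices must be unique within a session", call. = FALSE)
  }
  if (!all(events$kind %in% c("solvent", "odor", "qc"))) {
    stop("event kind must be one of 'solvent', 'odor', 'qc'", call. = FALSE)
  }
  if (!all(is.finite(events$amplitude_mV))) {
    stop("event amplitudes must be finite", call. = FALSE)
  }
  main <- events[events$kind != "qc", ]
  if (sum(main$kind == "solvent") < 2L) {
    stop("a session needs at least two solvent events", call. = FALSE)
  }
  if (main$kind[1L] != "solvent" || main$kind[nrow(main)] != "solvent") {
    stop("the first and last non-qc events must be solvent controls ",
         "(no extrapolation beyond solvent anchors is performed)",
         call. = FALSE)
  }
  structure(
    list(preparation_id = preparation_id, caste = caste,
         colony_id = colony_id, solvent_label = solvent_label,
         events = events, qc = qc),
    class = "eag_session"
  )
}

#' @export
print.eag_session <- function(x, ...) {
  cat(sprintf("<eag_session> preparation %s (%s, colony %s): %d events, %d solvent anchors\n",
              x$preparation_id, x$caste, x$colony_id, nrow(x$events),
              sum(x$events$kind == "solvent")))
  invisible(x)
}
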