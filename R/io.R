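#' Read EAG sessions from a tidy CSV
#'
#' Expected schema: `preparation_id`, `caste`, `colony`, `index`, `label`,
#' `kind`, `amplitude_mV`, one row per stimulus event. Caste labels are
#' normalized to canonical lower-case form. Optional columns `tetq_mV`
#' and `solvent_flank_mV` (constant within a preparation;
#' `solvent_flank_mV` semicolon-separated) populate the qc record.
#'
#' @param path CSV file path.
#' @return a named list of [eag_session()] objects.
#' @export
read_eag_sessions <- function(path) {
  df <- read_schema(path, c("preparation_id", "caste", "colony", "index",
                            "label", "kind", "amplitude_mV"))
  df$caste <- canonical_caste(df$caste)
  out <- lapply(split(df, df$preparation_id), function(d) {
    qc <- NULL
    if (all(c("tetq_mV", "solvent_flank_mV") %in% names(d)) &&
        !is.na(d$tetq_mV[1])) {
      qc <- list(tetq_mV = d$tetq_mV[1],
                 solvent_flank_mV = as.numeric(strsplit(
                   as.character(d$solvent_flank_mV[1]), ";")[[1]]))
    }
    eag_session(d$preparation_id[1], d$caste[1],
                d[, c("index", "label", "kind", "amplitude_mV")],
                colony_id = d$colony[1], qc = qc)
  })
  out[order(names(out))]
}

#' Write EAG sessions to a tidy CSV
#'
#' @param sessions list of [eag_session()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eag_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    d <- s$events
    d$preparation_id <- s$preparation_id
    d$caste <- s$caste
    d$colony <- s$colony_id
    d$tetq_mV <- if (!is.null(s$qc)) s$qc$tetq_mV else NA_real_
    d$solvent_flank_mV <- if (!is.null(s$qc))
      paste(s$qc$solvent_flank_mV, collapse = ";") else NA_character_
    d[, c("preparation_id", "caste", "colony", "index", "label", "kind",
          "amplitude_mV", "tetq_mV", "solvent_flank_mV")]
  })
  write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-frame detection stream
#'
#' Schema: `frame`, `x`, `y` (pixels).
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_detections <- function(path) {
  df <- read_schema(path, c("frame", "x", "y"))
  if (anyNA(df$x) || anyNA(df$y)) {
    stop("detections contain missing coordinates", call. = FALSE)
  }
  df[order(df$frame), ]
}

#' Read tracks, enforcing per-track frame monotonicity
#'
#' Schema: `track_id`, `frame`, `x`, `y`. Frames must be strictly
#' increasing within each track.
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_tracks <- function(path) {
  df <- read_schema(path, c("track_id", "frame", "x", "y"))
  bad <- vapply(split(df$frame, df$track_id),
                function(fr) any(diff(fr) <= 0), TRUE)
  if (any(bad)) {
    stop("non-monotone frame indices within track(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  df
}

#' Write tracks to CSV
#'
#' @param tracks tibble with `track_id`, `frame`, `x`, `y` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks[, c("track_id", "frame", "x", "y")]), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a blend-panel definition
#'
#' Schema: `blend_id`, `class`, `compound`, optional `cas`,
#' `concentration_M`; validated via [blend_panel()].
#' @param path CSV file path.
#' @return a [blend_panel()].
#' @export
read_blend_panel <- function(path) {
  blend_panel(read_schema(path, c("blend_id", "class", "compound")))
}

#' Write a blend panel to CSV
#' @param panel a [blend_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_blend_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read frame-wise aggression scores
#'
#' Schema: `trial_id`, `pairing`, `relation`, `frame`, `score` (binary),
#' with optional event rows supplied separately. Non-binary scores are a
#' row-level error.
#'
#' @param path CSV file path.
#' @param events_path optional CSV with `trial_id`, `event_type`
#'   (`dismemberment` or `death`), `frame`.
#' @return a list of trials compatible with [aggression_summary()].
#' @export
read_aggression_scores <- function(path, events_path = NULL) {
  df <- read_schema(path, c("trial_id", "pairing", "relation", "frame",
                            "score"))
  bad <- which(!df$score %in% c(0, 1))
  if (length(bad)) {
    stop("non-binary score(s) at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ev <- if (!is.null(events_path)) {
    read_schema(events_path, c("trial_id", "event_type", "frame"))
  } else NULL
  lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$frame), ]
    get_ev <- function(type) {
      if (is.null(ev)) return(integer(0))
      fr <- ev$frame[ev$trial_id == d$trial_id[1] & ev$event_type == type]
      if (any(fr < 0 | fr >= nrow(d))) {
        stop("event frame outside [0, n_frames) for trial ", d$trial_id[1],
             call. = FALSE)
      }
      as.integer(fr)
    }
    list(trial_id = d$trial_id[1], pairing = d$pairing[1],
         relation = d$relation[1], scores = as.integer(d$score),
         dismemberment_frames = get_ev("dismemberment"),
         death_frames = get_ev("death"))
  })
}

# Shared CSV reader with header validation.
read_schema <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
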