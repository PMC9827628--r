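#' Construct and validate a blend-panel definition
#'
#' A blend panel defines the odor stimuli of a screen: each blend is a set
#' of individual compounds of one functional chemical class, mixed at a
#' common molar concentration. The validator enforces the panel geometry
#' used by the screen design: every blend has between `min_members` and
#' `max_members` compounds and a single chemical class.
#'
#' @param panel data frame with columns `blend_id`, `class`, `compound`
#'   and optionally `cas`, `concentration_M` (filled with the default
#'   1e-3 M when absent).
#' @param min_members,max_members allowed per-blend compound counts
#'   (defaults 9 and 17).
#' @return a validated tibble of class `blend_panel` (one row per
#'   compound).
#' @export
blend_panel <- function(panel, min_members = 9, max_members = 17) {
  panel <- as_tibble(panel)
  need <- c("blend_id", "class", "compound")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"cas" %in% names(panel)) panel$cas <- NA_character_
  if (!"concentration_M" %in% names(panel)) panel$concentration_M <- 1e-3
  if (anyNA(panel$class)) stop("every blend needs a class label", call. = FALSE)
  per_blend <- dplyr::summarise(
    dplyr::group_by(panel, .data$blend_id),
    n = dplyr::n(), n_class = dplyr::n_distinct(.data$class), .groups = "drop")
  if (any(per_blend$n_class > 1L)) {
    stop("all compounds within a blend must share its chemical class",
         call. = FALSE)
  }
  bad <- per_blend$n < min_members | per_blend$n > max_members
  if (any(bad)) {
    stop("blend(s) outside the allowed member count [",
         min_members, ", ", max_members, "]: ",
         paste(per_blend$blend_id[bad], collapse = ", "), call. = FALSE)
  }
  class(panel) <- c("blend_panel", class(panel))
  panel
}

#' Audit a blend panel's geometry
#'
#' @param panel a [blend_panel()].
#' @return a list with `n_blends`, `n_compounds` (total across blends),
#'   `members` (named per-blend counts) and `classes` (blends per class).
#' @export
audit_blend_panel <- function(panel) {
  stopifnot(inherits(panel, "blend_panel"))
  members <- table(panel$blend_id)
  classes <- table(unique(panel[, c("blend_id", "class")])$class)
  list(n_blends = length(members), n_compounds = nrow(panel),
       members = members, classes = classes)
}

#' Synthetic 36-blend general-odorant panel
#'
#' A synthetic stand-in for a 36-blend, 390-compound general-odorant panel
#' organized by functional chemical class (alcohols, aldehydes, amines,
#' carboxylic acids, esters, ketones/indoles, lactones, a single alkane
#' blend, sulfurs and thiazoles). Compound entries are placeholders
#' (`<class>_<i>`), not real chemicals: only the panel geometry — the
#' blend/class layout and per-blend member counts between 9 and 17 summing
#' to 390 — is meaningful, which is what the panel-level statistics
#' consume.
#'
#' @return a [blend_panel()] tibble with 390 rows.
#' @export
synthetic_blend_panel <- function() {
  eff <- study_blend_effects()          # blend_id -> class layout
  members <- rep(11L, 36)
  members[c(1, 7, 13, 19, 25, 31)] <- 10L   # 36*11 - 6 = 390 compounds
  rows <- lapply(1:36, function(b) {
    tibble(blend_id = b, class = eff$class[b],
           compound = sprintf("%s_%02d_%02d", eff$class[b], b,
                              seq_len(members[b])),
           cas = NA_character_, concentration_M = 1e-3)
  })
  blend_panel(dplyr::bind_rows(rows))
}
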