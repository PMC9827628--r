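#' Assemble a caste-by-blend matrix of normalized responses
#'
#' Reshapes normalized odor responses (one row per preparation x blend)
#' into the long replicate table consumed by the panel statistics, keyed
#' by blend and caste, optionally joining chemical-class labels from a
#' blend panel.
#'
#' @param normalized tibble as returned by [normalize_sessions()]; blend
#'   ids are parsed from labels of the form `blend_07` (or an existing
#'   `blend_id` column is used).
#' @param panel optional [blend_panel()] supplying `class` per blend.
#' @return a tibble with columns `blend_id`, `class`, `caste`,
#'   `preparation_id`, `value_mV`, of class `caste_blend_matrix`.
#' @export
blend_matrix <- function(normalized, panel = NULL) {
  normalized <- as_tibble(normalized)
  if (!"blend_id" %in% names(normalized)) {
    normalized$blend_id <- as.integer(sub("^blend_", "", normalized$label))
    if (anyNA(normalized$blend_id)) {
      stop("could not parse blend ids from labels; provide a blend_id column",
           call. = FALSE)
    }
  }
  out <- normalized[, c("blend_id", "caste", "preparation_id", "value_mV")]
  out$caste <- canonical_caste(out$caste)
  if (!is.null(panel)) {
    cls <- unique(as_tibble(panel)[, c("blend_id", "class")])
    out <- dplyr::left_join(out, cls, by = "blend_id")
  } else {
    out$class <- NA_character_
  }
  out <- out[, c("blend_id", "class", "caste", "preparation_id", "value_mV")]
  class(out) <- c("caste_blend_matrix", class(out))
  out
}

#' Per-blend mean normalized responses by caste
#'
#' @param matrix a [blend_matrix()].
#' @return a tibble `blend_id`, `class`, `caste`, `n`, `mean_mV`,
#'   `sem_mV`.
#' @export
blend_means <- function(matrix) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(matrix), .data$blend_id, .data$class, .data$caste),
    n = dplyr::n(), mean_mV = mean(.data$value_mV),
    sem_mV = sd(.data$value_mV) / sqrt(dplyr::n()), .groups = "drop")
}

#' Caste comparison per blend: Welch tests with two-stage FDR
#'
#' For every blend, compares minor vs major replicate normalized responses
#' with Welch's unequal-variance two-sample t-test, then adjusts the
#' p-values across blends with the adaptive two-stage step-up FDR
#' ([fdr_two_stage()]). Blends with fewer than two replicates in either
#' caste are excluded with a warning.
#'
#' @param matrix a [blend_matrix()].
#' @param alpha FDR level (default 0.05).
#' @param fdr_method `"two-stage"` (default) or `"bh"`.
#' @return a tibble with one row per blend: `blend_id`, `class`,
#'   `mean_minor`, `mean_major`, `welch_t` (positive when minors respond
#'   more), `df`, `p_value`, `q_value`, `significant`, `higher_caste`.
#' @export
compare_castes <- function(matrix, alpha = 0.05,
                           fdr_method = c("two-stage", "bh")) {
  fdr_method <- match.arg(fdr_method)
  m <- as_tibble(matrix)
  counts <- dplyr::count(m, .data$blend_id, .data$caste)
  wide_n <- tidyr::pivot_wider(counts, names_from = "caste",
                               values_from = "n", values_fill = 0L)
  for (cc in .castes) if (!cc %in% names(wide_n)) wide_n[[cc]] <- 0L
  drop <- wide_n$blend_id[wide_n$minor < 2L | wide_n$major < 2L]
  if (length(drop)) {
    warning("excluding blend(s) with <2 replicates in a caste: ",
            paste(drop, collapse = ", "), call. = FALSE)
    m <- m[!m$blend_id %in% drop, ]
  }
  res <- lapply(split(m, m$blend_id), function(d) {
    x <- d$value_mV[d$caste == "minor"]
    y <- d$value_mV[d$caste == "major"]
    tt <- t.test(x, y, var.equal = FALSE)
    tibble(blend_id = d$blend_id[1L], class = d$class[1L],
           mean_minor = mean(x), mean_major = mean(y),
           welch_t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(out$blend_id), ]
  adj <- fdr_two_stage(out$p_value, alpha = alpha, method = fdr_method)
  out$q_value <- adj$q
  out$significant <- adj$significant
  out$higher_caste <- ifelse(out$mean_minor >= out$mean_major, "minor", "major")
  out
}

#' Classify each blend response against the solvent baseline
#'
#' One-sample t-tests of the replicate normalized responses against zero,
#' per blend and caste, FDR-adjusted within caste, combined with the sign
#' of the mean to yield four categories: `sig_above`, `ns_above`,
#' `ns_below`, `sig_below`. A zero-variance replicate vector cannot be
#' tested; its category falls back to the sign of the mean with `q = NA`
#' and is flagged in `degenerate`.
#'
#' @inheritParams compare_castes
#' @return a list with `classification` (tibble: `blend_id`, `caste`,
#'   `mean_mV`, `p_value`, `q_value`, `category`, `degenerate`) and
#'   `counts` (category tallies per caste).
#' @export
classify_vs_solvent <- function(matrix, alpha = 0.05,
                                fdr_method = c("two-stage", "bh")) {
  fdr_method <- match.arg(fdr_method)
  m <- as_tibble(matrix)
  per <- dplyr::group_by(m, .data$blend_id, .data$caste)
  res <- dplyr::summarise(per, n = dplyr::n(), mean_mV = mean(.data$value_mV),
                          sd_mV = sd(.data$value_mV), .groups = "drop")
  if (any(res$n < 2L)) {
    stop("every (blend, caste) cell needs >= 2 replicates", call. = FALSE)
  }
  res$degenerate <- res$sd_mV == 0
  res$p_value <- NA_real_
  for (i in seq_len(nrow(res))) {
    if (res$degenerate[i]) next
    d <- m[m$blend_id == res$blend_id[i] & m$caste == res$caste[i], ]
    res$p_value[i] <- t.test(d$value_mV, mu = 0)$p.value
  }
  res$q_value <- NA_real_
  for (cc in unique(res$caste)) {
    idx <- res$caste == cc
    res$q_value[idx] <- fdr_two_stage(res$p_value[idx], alpha = alpha,
                                      method = fdr_method)$q
  }
  sig <- !is.na(res$q_value) & res$q_value <= alpha
  res$category <- ifelse(res$mean_mV >= 0,
                         ifelse(sig, "sig_above", "ns_above"),
                         ifelse(sig, "sig_below", "ns_below"))
  classification <- res[, c("blend_id", "caste", "mean_mV", "p_value",
                            "q_value", "category", "degenerate")]
  counts <- dplyr::count(classification, .data$caste, .data$category)
  counts <- tidyr::complete(
    counts, caste = unique(classification$caste),
    category = c("sig_above", "ns_above", "ns_below", "sig_below"),
    fill = list(n = 0L))
  list(classification = classification, counts = counts)
}

#' Fisher's exact test on sub-solvent response proportions
#'
#' Builds the 2x2 table of blends by response sign (sub-solvent, i.e.
#' negative mean, vs above-solvent) for the two castes and tests for a
#' caste difference in the proportion of sub-solvent blends with the
#' two-sided exact hypergeometric test. A table with a zero margin carries
#' no information about association: p is 1 and the result is flagged
#' degenerate.
#'
#' @param class_minor,class_major classification tibbles for each caste,
#'   as in the `classification` element of [classify_vs_solvent()]
#'   (columns `blend_id`, `mean_mV` or `category`); must cover the same
#'   blend set.
#' @return a list with `table` (2x2 integer matrix, rows = caste,
#'   cols = sub/above), `odds_ratio`, `p_value`, `degenerate`.
#' @export
sub_solvent_fisher <- function(class_minor, class_major) {
  a <- as_tibble(class_minor); b <- as_tibble(class_major)
  if (!setequal(a$blend_id, b$blend_id) || nrow(a) != nrow(b)) {
    stop("the two castes must cover the same blend set", call. = FALSE)
  }
  sub_a <- sum(a$mean_mV < 0); sub_b <- sum(b$mean_mV < 0)
  tab <- matrix(c(sub_a, nrow(a) - sub_a, sub_b, nrow(b) - sub_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(caste = c("minor", "major"),
                                response = c("sub_solvent", "above_solvent")))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       degenerate = FALSE)
}

#' Number of unordered pairs among n items
#'
#' @param n_items item count (>= 2).
#' @return `n_items * (n_items - 1) / 2`.
#' @examples
#' count_pairs(36)  # 630
#' @export
count_pairs <- function(n_items) {
  if (length(n_items) != 1L || is.na(n_items) || n_items < 2) {
    stop("n_items must be a single number >= 2", call. = FALSE)
  }
  n_items * (n_items - 1) / 2
}

#' Rank concordance between castes with per-pair labels
#'
#' For every unordered pair of blends (i, j), the pair is concordant when
#' the two castes order the blends' mean responses the same way
#' (`(x_i - x_j) * (y_i - y_j) > 0`), discordant when they order them
#' oppositely, and tied when either caste gives an exactly equal response.
#' Kendall's tie-corrected tau-b summarizes the pair counts; its p-value
#' uses the normal approximation with tie-corrected variance of the S
#' statistic.
#'
#' @param means_minor,means_major per-blend mean normalized responses
#'   (equal-length numeric vectors, >= 2 blends, aligned by position);
#'   names (or `blend_ids`) identify the blends.
#' @param blend_ids optional blend identifiers (default names of
#'   `means_minor`, else `1:n`).
#' @return a list of class `concordance_result`: `n_items`, `n_pairs`,
#'   `n_concordant`, `n_discordant`, `n_tied`, `tau_b`, `p_value`, and
#'   `pairs` (tibble `blend_i`, `blend_j`, `label`).
#' @export
concordance_analysis <- function(means_minor, means_major, blend_ids = NULL) {
  x <- as.numeric(means_minor); y <- as.numeric(means_major)
  n <- length(x)
  if (length(y) != n) stop("caste mean vectors differ in length", call. = FALSE)
  if (n < 2) stop("need at least 2 blends", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("means must be non-missing", call. = FALSE)
  flag_constant <- length(unique(x)) == 1L || length(unique(y)) == 1L
  ids <- blend_ids %||% names(means_minor) %||% seq_len(n)

  ij <- t(utils::combn(n, 2))   # canonical (i, j) order, i < j
  dx <- x[ij[, 1]] - x[ij[, 2]]
  dy <- y[ij[, 1]] - y[ij[, 2]]
  s <- sign(dx) * sign(dy)
  label <- ifelse(s > 0, "concordant", ifelse(s < 0, "discordant", "tied"))
  pairs <- tibble(blend_i = ids[ij[, 1]], blend_j = ids[ij[, 2]],
                  label = label)
  nc <- sum(s > 0); nd <- sum(s < 0); nt <- sum(s == 0)

  if (flag_constant) {
    tau_b <- NA_real_; p <- NA_real_
  } else {
    # Tie-corrected tau-b and the normal approximation for S = C - D.
    tx <- table(x); ty <- table(y)
    n0 <- n * (n - 1) / 2
    n1 <- sum(tx * (tx - 1) / 2)
    n2 <- sum(ty * (ty - 1) / 2)
    S <- nc - nd
    tau_b <- S / sqrt((n0 - n1) * (n0 - n2))
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- if (n > 2) {
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2))
    } else 0
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    p <- if (var_s > 0) 2 * pnorm(abs(S) / sqrt(var_s), lower.tail = FALSE)
         else NA_real_
  }
  structure(list(n_items = n, n_pairs = nrow(pairs), n_concordant = nc,
                 n_discordant = nd, n_tied = nt, tau_b = tau_b, p_value = p,
                 constant_input = flag_constant, pairs = pairs),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %d items, %d pairs: %d concordant, %d discordant, %d tied\n",
    x$n_items, x$n_pairs, x$n_concordant, x$n_discordant, x$n_tied))
  if (x$constant_input) cat("  tau-b undefined (constant input vector)\n")
  else cat(sprintf("  tau-b = %.4f, p = %.3g\n", x$tau_b, x$p_value))
  invisible(x)
}

#' Discordance proportion per chemical class
#'
#' For each chemical class C with k member blends in an n-blend panel,
#' the class's pair set is every pair with at least one member in C
#' (size `k * (n - k) + k * (k - 1) / 2`); the discordance proportion is
#' the fraction of those pairs labelled discordant by
#' [concordance_analysis()].
#'
#' @param pairs per-pair label tibble (`blend_i`, `blend_j`, `label`)
#'   from [concordance_analysis()].
#' @param panel a [blend_panel()] (or any table with unique
#'   `blend_id`, `class` rows) covering every blend in `pairs`.
#' @return a tibble `class`, `n_blends`, `n_pairs`, `n_discordant`,
#'   `proportion`.
#' @export
per_class_discordance <- function(pairs, panel) {
  cls <- unique(as_tibble(panel)[, c("blend_id", "class")])
  ids <- unique(c(pairs$blend_i, pairs$blend_j))
  unlabelled <- setdiff(ids, cls$blend_id)
  if (length(unlabelled)) {
    stop("blend(s) without a class label: ",
         paste(unlabelled, collapse = ", "), call. = FALSE)
  }
  lut <- setNames(cls$class, cls$blend_id)
  ci <- lut[as.character(pairs$blend_i)]
  cj <- lut[as.character(pairs$blend_j)]
  out <- lapply(sort(unique(cls$class[cls$blend_id %in% ids])), function(cc) {
    inset <- ci == cc | cj == cc
    tibble(class = cc,
           n_blends = sum(lut[as.character(ids)] == cc),
           n_pairs = sum(inset),
           n_discordant = sum(inset & pairs$label == "discordant"),
           proportion = sum(inset & pairs$label == "discordant") / sum(inset))
  })
  dplyr::bind_rows(out)
}
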