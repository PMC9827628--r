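#' Two-stage step-up false discovery rate control
#'
#' Adjusts a vector of p-values using the adaptive two-stage linear step-up
#' procedure of Benjamini, Krieger and Yekutieli (2006, Definition 6), the
#' multiple-comparison correction used throughout the odor-panel statistics.
#' The first stage runs a Benjamini-Hochberg step-up at level
#' `alpha / (1 + alpha)` to estimate the number of true null hypotheses `m0`;
#' the second stage reruns the step-up at the level inflated by `m / m0`.
#'
#' The returned q-values are on the scale of `alpha`: a hypothesis is
#' rejected iff `q <= alpha`. On a single test `q >= p` always holds.
#'
#' @param p numeric vector of p-values in `[0, 1]`. `NA`s are propagated.
#' @param alpha target FDR level (default 0.05).
#' @param method `"two-stage"` (adaptive, the default) or `"bh"` for the
#'   single-stage Benjamini-Hochberg procedure, kept for sensitivity analysis.
#' @return a list with elements `q` (adjusted p-values, same length/order as
#'   `p`), `significant` (logical, `q <= alpha`), `m0` (estimated number of
#'   true nulls; `NA` for `method = "bh"`) and `alpha` (the level used).
#' @examples
#' fdr_two_stage(c(0.001, 0.02, 0.04, 0.2))$significant
#' @export
fdr_two_stage <- function(p, alpha = 0.05, method = c("two-stage", "bh")) {
  method <- match.arg(method)
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop_config("alpha", "must be in (0, 1)")

  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) {
    return(list(q = q, significant = rep(NA, length(p)), m0 = NA_integer_,
                alpha = alpha))
  }

  if (method == "bh") {
    q[ok] <- p.adjust(pv, method = "BH")
    return(list(q = q, significant = q <= alpha, m0 = NA_integer_,
                alpha = alpha))
  }

  fact <- 1 + alpha
  alpha_prime <- alpha / fact
  bh <- p.adjust(pv, method = "BH")
  r1 <- sum(bh <= alpha_prime)

  if (r1 == 0L || r1 == m) {
    # All-null or all-signal first stage: keep stage-1 adjustment.
    qv <- pmin(bh * fact, 1)
    m0 <- m - r1
  } else {
    m0 <- m - r1
    # Stage 2: step-up at alpha_prime * m / m0; equivalently rescale BH.
    qv <- pmin(bh * (m0 / m) * fact, 1)
  }
  q[ok] <- qv
  list(q = q, significant = q <= alpha, m0 = as.integer(m0), alpha = alpha)
}
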