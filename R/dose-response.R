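#' Four-parameter logistic and hormetic dose-response fits
#'
#' Fits solvent-normalized responses against log10 molar dose with the
#' four-parameter logistic (4PL, Hill) model
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{(log10EC50 - x) \cdot hill}),}
#' `x = log10(dose)`, by bounded least squares. The hormetic variant adds
#' a linear term `slope * x` to the 4PL, allowing a non-monotonic
#' dip-then-recover profile; with `model = "auto"` both are fitted and the
#' one with the lower small-sample AICc is reported.
#'
#' The monotonic flag is `TRUE` only when both the fitted curve (evaluated
#' on a fine dose grid) and the per-dose mean responses are monotone
#' (non-decreasing or non-increasing); a decrease-then-rise pattern in the
#' dose means marks the fit non-monotonic (hormesis pattern).
#'
#' @param doses molar concentrations (> 0; >= 4 distinct values for the
#'   4PL). May contain replicates.
#' @param responses normalized responses (mV), same length as `doses`.
#' @param model `"4PL"`, `"hormetic"` or `"auto"`.
#' @param hill_bounds positive bounds on |hill| (default `c(0.1, 10)`).
#' @return a list of class `dose_response_fit` with elements `model`,
#'   `parameters` (named: `bottom`, `top`, `log10ec50`, `hill`, and
#'   `slope` for the hormetic model), `monotonic`, `rss`, `aicc`,
#'   `fitted` (at the data doses), `candidates` (per-model AICc table),
#'   `doses`, `responses`.
#' @export
fit_dose_response <- function(doses, responses,
                              model = c("auto", "4PL", "hormetic"),
                              hill_bounds = c(0.1, 10)) {
  model <- match.arg(model)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  x <- log10(doses); y <- responses
  k_distinct <- length(unique(x))
  need <- if (model == "hormetic") 5L else 4L
  if (k_distinct < need) {
    stop(sprintf(
      "only %d distinct doses for a %d-parameter model; fix parameters or add doses",
      k_distinct, need), call. = FALSE)
  }

  fits <- list()
  if (model %in% c("auto", "4PL")) fits[["4PL"]] <- fit_4pl(x, y, hill_bounds)
  if (model %in% c("auto", "hormetic") && k_distinct >= 5L) {
    fits[["hormetic"]] <- fit_hormetic(x, y, hill_bounds)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("dose-response fit failed to converge", call. = FALSE)
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  best_name <- if (any(is.finite(aiccs))) {
    names(which.min(aiccs))
  } else {
    # too few points for the small-sample criterion: fall back to RSS
    names(which.min(vapply(fits, function(f) f$rss, 0)))
  }
  best <- fits[[best_name]]

  grid <- seq(min(x), max(x), length.out = 201)
  curve_grid <- eval_dose_curve(best$parameters, grid, best_name)
  dm <- as.numeric(tapply(y, x, mean))  # tapply orders by sorted dose
  monotone <- function(v) all(diff(v) >= 0) || all(diff(v) <= 0)
  monotonic <- monotone(curve_grid) && monotone(dm)

  structure(list(
    model = best_name, parameters = best$parameters, monotonic = monotonic,
    rss = best$rss, aicc = best$aicc,
    fitted = eval_dose_curve(best$parameters, x, best_name),
    candidates = tibble(model = names(fits), aicc = unname(aiccs)),
    doses = doses, responses = responses
  ), class = "dose_response_fit")
}

# Evaluate the fitted curve at log10-dose positions.
eval_dose_curve <- function(p, x, model) {
  base <- p[["bottom"]] +
    (p[["top"]] - p[["bottom"]]) / (1 + 10^((p[["log10ec50"]] - x) * p[["hill"]]))
  if (model == "hormetic") base + p[["slope"]] * x else base
}

aicc_from_rss <- function(rss, n, k) {
  # Gaussian log-likelihood AIC with small-sample correction; k includes sigma.
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

fit_4pl <- function(x, y, hill_bounds) {
  starts <- expand.grid(hill = c(1, -1, 0.5, 2),
                        e = unname(quantile(x, c(0.25, 0.5, 0.75))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((log10ec50 - x) * hill)),
        start = list(bottom = min(y), top = max(y),
                     log10ec50 = starts$e[i], hill = starts$hill[i]),
        lower = c(bottom = min(y) - 2 * diff(range(y)) - 1e-6,
                  top = min(y) - 2 * diff(range(y)) - 1e-6,
                  log10ec50 = min(x) - 3, hill = -hill_bounds[2]),
        upper = c(bottom = max(y) + 2 * diff(range(y)) + 1e-6,
                  top = max(y) + 2 * diff(range(y)) + 1e-6,
                  log10ec50 = max(x) + 3, hill = hill_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(parameters = coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  best$aicc <- aicc_from_rss(best$rss, length(y), 5)
  best
}

fit_hormetic <- function(x, y, hill_bounds) {
  starts <- expand.grid(hill = c(1, -1),
                        e = unname(quantile(x, c(0.35, 0.65))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((log10ec50 - x) * hill)) +
          slope * x,
        start = list(bottom = min(y), top = max(y), log10ec50 = starts$e[i],
                     hill = starts$hill[i], slope = 0),
        lower = c(-Inf, -Inf, min(x) - 3, -hill_bounds[2], -Inf),
        upper = c(Inf, Inf, max(x) + 3, hill_bounds[2], Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(parameters = coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(NULL)
  best$aicc <- aicc_from_rss(best$rss, length(y), 6)
  best
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> model %s (%s)\n", x$model,
              if (x$monotonic) "monotonic" else "non-monotonic"))
  print(round(x$parameters, 4))
  invisible(x)
}
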