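#' Plot an occupancy density map
#'
#' Renders a [density_map()] as a filled raster in arena coordinates,
#' dark-to-bright with occupancy, optionally overlaying the trail band.
#'
#' @param map a [density_map()].
#' @param cal optional [arena_calibration()]; when supplied the trail
#'   band edges are drawn as dashed lines.
#' @return a ggplot object.
#' @export
plot_density_map <- function(map, cal = NULL) {
  stopifnot(inherits(map, "density_map"))
  xc <- (head(map$x_breaks, -1) + tail(map$x_breaks, -1)) / 2
  yc <- (head(map$y_breaks, -1) + tail(map$y_breaks, -1)) / 2
  df <- expand.grid(y_cm = yc, x_cm = xc)
  df$density <- as.vector(map$density)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_cm, .data$y_cm,
                                        fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "occupancy")
  if (!is.null(cal)) {
    p <- p + ggplot2::geom_vline(
      xintercept = cal$arena_w_cm / 2 + c(-1, 1) * cal$band_half_width_cm,
      linetype = "dashed", colour = "white")
  }
  p
}

#' Plot a dose-response fit
#'
#' Shows per-dose mean responses with standard-error bars and the fitted
#' curve on a log10 dose axis.
#'
#' @param fit a [fit_dose_response()] result.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  x <- log10(fit$doses)
  agg <- tibble(
    log10_dose = sort(unique(x)),
    mean = as.numeric(tapply(fit$responses, x, mean)),
    sem = as.numeric(tapply(fit$responses, x,
                            function(v) sd(v) / sqrt(length(v))))
  )
  grid <- seq(min(x), max(x), length.out = 200)
  curve_df <- tibble(log10_dose = grid,
                     value = eval_dose_curve(fit$parameters, grid, fit$model))
  ggplot2::ggplot(agg, ggplot2::aes(.data$log10_dose, .data$mean)) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(.data$log10_dose, .data$value),
                       colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log10 dose (M)", y = "normalized response (mV)")
}
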