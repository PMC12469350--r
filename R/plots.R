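#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline labs theme_minimal
#' @export
ggplot2::autoplot

fitted_curve_plot <- function(data, grid, ylab, xlab) {
  ggplot(data, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 1.4, alpha = 0.8) +
    geom_line(data = grid, aes(x = .data$x, y = .data$y), color = "#c0392b") +
    labs(x = xlab, y = ylab) +
    theme_minimal()
}

#' Plot methods
#'
#' `autoplot()` methods draw each fitted object with its data and fitted
#' curve; [plot_per_residue()] draws a per-residue score bar plot with
#' optional threshold lines (the style of protection-factor and CSP
#' figures).
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name acpdyn-plots
NULL

#' @rdname acpdyn-plots
#' @export
autoplot.lem_fit <- function(object, ...) {
  d <- tibble(x = object$data$D, y = object$data$y)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  g <- tibble(x = xs, y = lem_signal(xs, object$dG_H2O, object$m_value,
                                     object$aN, object$bN, object$aU, object$bU,
                                     object$temperature))
  fitted_curve_plot(d, g, "signal", "[denaturant] (M)")
}

#' @rdname acpdyn-plots
#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- tibble(x = object$data$T, y = object$data$y)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  g <- tibble(x = xs, y = melt_signal(xs, object$Tm, object$dH_vH,
                                      object$aN, object$bN, object$aU, object$bU))
  fitted_curve_plot(d, g, "ellipticity", "temperature (K)")
}

#' @rdname acpdyn-plots
#' @export
autoplot.dsc_result <- function(object, ...) {
  d <- tibble(x = object$excess$T, y = object$excess$Cp_exc)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    labs(x = "temperature (K)", y = "excess Cp (kcal/mol/K)") +
    theme_minimal()
}

#' @rdname acpdyn-plots
#' @export
autoplot.dsc_fit <- function(object, ...) {
  d <- tibble(x = object$data$T, y = object$data$y)
  xs <- seq(min(d$x), max(d$x), length.out = 300)
  g <- tibble(x = xs, y = dsc_excess_model(xs, object$Tm, object$dH_vH, object$dH_cal))
  fitted_curve_plot(d, g, "excess Cp (kcal/mol/K)", "temperature (K)")
}

#' @rdname acpdyn-plots
#' @param data Tibble with `residue` and a value column.
#' @param value Column name (string) to plot (default `"value"`).
#' @param thresholds Optional numeric vector drawn as dashed lines.
#' @export
plot_per_residue <- function(data, value = "value", thresholds = NULL, ...) {
  p <- ggplot(data, aes(x = .data$residue, y = .data[[value]])) +
    geom_col(width = 0.8, fill = "#34495e") +
    labs(x = "residue", y = value) +
    theme_minimal()
  for (thr in thresholds) {
    p <- p + geom_hline(yintercept = thr, linetype = "dashed", color = "#c0392b")
  }
  p
}
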