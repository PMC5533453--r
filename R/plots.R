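# ggplot2 visualisations for the main result types.

#' Scree diagram of an SSA decomposition
#'
#' Ordered fractional partial variances on log10-log10 axes, the standard
#' diagnostic for trend / circadian-pair / ultradian-tail structure.
#'
#' @param object An `ssa_decomp`.
#' @param band Optional two-element `log10(k)` range to shade (e.g.
#'   `c(1.4, 1.6)` for the 60-90-min ultradian band).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssa_decomp <- function(object, band = NULL, ...) {
  s <- ssa_scree(object)
  p <- ggplot2::ggplot(s, ggplot2::aes(log10(.data$k), log10(.data$lambda_frac))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(log[10](k)),
                  y = expression(log[10](lambda[k] / lambda[tot])),
                  title = "SSA scree diagram") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "orange")
  }
  p
}

#' Data, cosinor curve and SSA circadian reconstruction of one subject
#'
#' @param object Tibble from [circadian_reconstruction()].
#' @param fit Optional `cosinor_fit` overlaid as a dashed curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_circadian <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_min / 1440)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$counts), colour = "grey70",
                       linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend + .data$circadian),
                       colour = "steelblue", linewidth = 0.7) +
    ggplot2::labs(x = "time (days)", y = "counts/min",
                  title = "SSA trend + circadian reconstruction") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(object, yhat = predict(fit, object$time_min)),
      ggplot2::aes(y = .data$yhat), linetype = "dashed", colour = "firebrick")
  }
  p
}

#' IV(P) curve(s)
#'
#' @param object An `iv_curve` tibble (optionally several stacked, with a
#'   `group` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_curve <- function(object, ...) {
  aes <- if ("group" %in% names(object)) {
    ggplot2::aes(.data$P, .data$iv, colour = .data$group)
  } else {
    ggplot2::aes(.data$P, .data$iv)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "resampling interval P (min)", y = "IV(P)",
                  title = "Intradaily variability vs sampling interval") +
    ggplot2::theme_minimal()
}

#' Mean 24-hour profile with significance shading
#'
#' @param object A `profile_24h`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_24h <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(.data$minute / 60, .data$mean,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "hour of day", y = "mean counts/min",
                  title = "Mean 24h activity profile") +
    ggplot2::theme_minimal()
  if (nrow(object$intervals)) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_min / 60, xmax = .data$end_min / 60,
                   ymin = -Inf, ymax = Inf), alpha = 0.15, fill = "orange")
  }
  p
}
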