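#' Plot a tachogram
#'
#' Intervals against beat time, with out-of-bounds intervals highlighted and
#' gaps shaded.
#'
#' @param object An `rr_series`.
#' @param bounds A [physio_bounds()] object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot rr_series
#' @export
autoplot.rr_series <- function(object, bounds = physio_bounds(), ...) {
  df <- tibble::as_tibble(object)
  df$status <- ifelse(df$rr < bounds$rr_min, "short",
                      ifelse(df$rr > bounds$rr_max, "long", "ok"))
  gaps <- detect_gaps(object, bounds)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rr))
  if (nrow(gaps)) {
    p <- p + ggplot2::geom_rect(
      data = gaps, inherit.aes = FALSE, alpha = 0.15, fill = "grey40",
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf))
  }
  p +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(ok = "black", short = "firebrick", long = "darkorange"),
      guide = if (all(df$status == "ok")) "none" else "legend") +
    ggplot2::geom_hline(yintercept = c(bounds$rr_min, bounds$rr_max),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "RR interval (s)",
                  title = rr_label(object))
}

#' Poincare plot with fitted SD1/SD2 ellipse
#'
#' Each interval against its successor, the identity line, and the ellipse
#' whose semi-axes are SD1 (perpendicular to the identity) and SD2 (along
#' it), centred on the mean interval.
#'
#' @param series An `rr_series`.
#' @return A ggplot object.
#' @export
plot_poincare <- function(series) {
  series <- as_rr_series(series)
  rr <- series$rr
  df <- tibble::tibble(x = rr[-length(rr)], y = rr[-1])
  ps <- poincare_sd(rr)
  m <- mean(rr)
  th <- seq(0, 2 * pi, length.out = 181)
  ell <- tibble::tibble(
    x = m + (ps$sd2 / 1000) * cos(th) * cos(pi / 4) -
      (ps$sd1 / 1000) * sin(th) * sin(pi / 4),
    y = m + (ps$sd2 / 1000) * cos(th) * sin(pi / 4) +
      (ps$sd1 / 1000) * sin(th) * cos(pi / 4))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_path(data = ell, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(RR[i] ~ "(s)"), y = expression(RR[i + 1] ~ "(s)"),
                  subtitle = sprintf("SD1 = %.1f ms, SD2 = %.1f ms",
                                     ps$sd1, ps$sd2))
}

#' Plot F1 against missing-data percentage per reconstruction method
#'
#' @param object An `hrv_grid` from [run_grid()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hrv_grid
#' @export
autoplot.hrv_grid <- function(object, ...) {
  ggplot2::ggplot(object$f1,
                  ggplot2::aes(x = .data$missing_pct, y = .data$f1,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$f1_original, linetype = "dotted") +
    ggplot2::labs(x = "missing data (%)", y = "validation F1",
                  colour = "method")
}
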