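#' Plot a recovery curve
#'
#' @param object a [frap_curve()].
#' @param log_log plot both axes on log scale (short-time diagnostics).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.frap_curve <- function(object, log_log = FALSE, ...) {
  m <- curve_meta(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$intensity)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("time (%s)", m$units[["time"]]),
      y = "normalised fluorescence",
      title = sprintf("FRAP recovery, R = %g %s (%s)",
                      m$bleach_radius, m$units[["length"]], m$provenance)
    )
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a fit with its residual trace
#'
#' @param object a `frap_fit`.
#' @param log_log log–log axes (discrimination is easiest at short and
#'   long times).
#' @param ... unused.
#' @return A ggplot of data, fitted curve and residuals.
#' @export
autoplot.frap_fit <- function(object, log_log = FALSE, ...) {
  d <- tibble::tibble(
    time = object$curve$time, observed = object$curve$intensity,
    fitted = object$fitted, residual = object$residuals
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        size = 0.7, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(
      x = "time", y = "normalised fluorescence",
      title = sprintf("%s fit, R = %g, reduced chi2 = %.3g",
                      object$model_key, object$bleach_radius,
                      object$chi2_reduced)
    )
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a parameter-vs-1/R regression
#'
#' @param object a `vr_regression`.
#' @param ... unused.
#' @return A ggplot of the per-radius estimates, the fitted line and the
#'   1/R = 0 intercept.
#' @export
autoplot.vr_regression <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$inv_R, .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "red") +
    ggplot2::annotate("point", x = 0, y = object$intercept, shape = 4,
                      size = 3, colour = "blue") +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(
      x = "1 / R", y = object$parameter,
      title = sprintf("%s vs 1/R: slope %.3g, intercept %.3g",
                      object$parameter, object$slope, object$intercept)
    )
}

#' @export
plot.frap_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.frap_fit <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.vr_regression <- function(x, ...) print(autoplot(x, ...))
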