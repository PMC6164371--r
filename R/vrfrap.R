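#' Fit a set of recovery curves at several bleach radii
#'
#' Applies [fit_recovery()] to every curve of a variable-radius dataset
#' and collects the per-curve parameter estimates into one tidy table,
#' the input to [regress_vs_inverse_radius()].
#'
#' @param curves a list of [frap_curve()] objects, or a dataset tibble
#'   from [generate_vrfrap_dataset()] (with a `curve` list-column).
#' @param model_key `"adm"`, `"bm"` or `"rbm"`.
#' @param options a [fit_options()].
#' @return Tibble of class `vr_series`: one row per (radius, parameter)
#'   estimate with columns `bleach_radius`, `replicate`, `term`,
#'   `estimate`, `std_error`, `chi2_reduced`, `converged`, `model`, plus a
#'   `fit` list-column on the per-curve rows accessible via
#'   `attr(, "fits")`.
#' @export
fit_vr_series <- function(curves, model_key, options = fit_options()) {
  model_key <- match.arg(model_key, c("adm", "bm", "rbm"))
  if (is.data.frame(curves) && "curve" %in% names(curves)) {
    curves <- curves$curve
  }
  if (!length(curves)) abort("no curves supplied.")
  fits <- lapply(curves, fit_recovery, model_key = model_key, options = options)
  rows <- purrr::imap_dfr(fits, function(f, i) {
    est <- f$estimates
    tibble::tibble(
      curve_id = i, bleach_radius = f$bleach_radius, model = f$model_key,
      term = est$term, estimate = est$estimate, std_error = est$std_error,
      at_bound = est$at_bound, chi2_reduced = f$chi2_reduced,
      converged = f$converged
    )
  })
  # replicate index within radius
  rows <- rows |>
    dplyr::group_by(.data$bleach_radius, .data$term) |>
    dplyr::mutate(replicate = match(.data$curve_id, unique(.data$curve_id))) |>
    dplyr::ungroup()
  attr(rows, "fits") <- fits
  class(rows) <- c("vr_series", class(rows))
  rows
}

#' Regress a fitted parameter against inverse bleach radius
#'
#' Ordinary least squares of the per-curve estimates of one parameter
#' against 1/R, optionally restricted to radii above `r_min` (finite-size
#' effects bend the relation at small R) and optionally weighted by the
#' inverse squared per-fit standard errors.
#'
#' @param series a `vr_series` from [fit_vr_series()], or any data frame
#'   with columns `bleach_radius`, `term`, `estimate` (and `std_error`
#'   for weighting).
#' @param parameter which parameter to regress: `"alpha"`, `"D"`,
#'   `"D_alpha"`, `"M"` or `"K"`.
#' @param r_min keep only radii strictly greater than this; `NULL`
#'   (default) uses all radii. Simulation-side analyses conventionally use
#'   `r_min = 1` a.u.
#' @param weighted use 1/std_error^2 weights when available.
#' @param drop_bound drop estimates whose fit was pinned to a parameter
#'   bound (boundary-censored fits bias the slope; meaningful boundary
#'   values such as M = 1 for purely Brownian data argue for the default
#'   `FALSE`).
#' @return Object of class `vr_regression`: slope, intercept, their
#'   standard errors, r-squared, the radii used, and the underlying `lm`.
#' @export
#' @examples
#' s <- tibble::tibble(bleach_radius = c(0.32, 0.37, 0.44, 0.74),
#'                     term = "M",
#'                     estimate = 0.75 + 0.63 * 0.09 / bleach_radius)
#' regress_vs_inverse_radius(s, "M")
regress_vs_inverse_radius <- function(series, parameter, r_min = NULL,
                                      weighted = FALSE, drop_bound = FALSE) {
  parameter <- match.arg(parameter, c("alpha", "D", "D_alpha", "M", "K"))
  d <- dplyr::filter(
    as.data.frame(series),
    .data$term == parameter, is.finite(.data$estimate)
  )
  if (drop_bound && "at_bound" %in% names(d)) {
    d <- d[!d$at_bound, , drop = FALSE]
  }
  if (!is.null(r_min)) d <- d[d$bleach_radius > r_min, , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 usable (radius, estimate) points.")
  if (length(unique(d$bleach_radius)) < 2) {
    abort("degenerate series: all radii identical.")
  }
  d$inv_R <- 1 / d$bleach_radius
  w <- NULL
  if (weighted && "std_error" %in% names(d) &&
      all(is.finite(d$std_error)) && all(d$std_error > 0)) {
    w <- 1 / d$std_error^2
  }
  fit <- lm(estimate ~ inv_R, data = d, weights = w)
  cf <- summary(fit)$coefficients
  structure(
    list(
      parameter = parameter,
      intercept = cf[1, 1], intercept_stderr = cf[1, 2],
      slope = cf[2, 1], slope_stderr = cf[2, 2],
      r_squared = summary(fit)$r.squared,
      n_points = nrow(d), r_min = r_min,
      radii = sort(unique(d$bleach_radius)),
      lm = fit, data = tibble::as_tibble(d)
    ),
    class = "vr_regression"
  )
}

#' @export
print.vr_regression <- function(x, ...) {
  cat(sprintf(
    "<vr_regression: %s ~ 1/R> slope = %.4g (se %.3g), intercept = %.4g (se %.3g), r2 = %.3f, n = %d\n",
    x$parameter, x$slope, x$slope_stderr, x$intercept, x$intercept_stderr,
    x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Tidy a variable-radius regression
#' @param x a `vr_regression`.
#' @param ... unused.
#' @return Tibble with one row per coefficient.
#' @export
tidy.vr_regression <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$intercept_stderr, x$slope_stderr)
  )
}

#' One-row regression summary
#' @param x a `vr_regression`.
#' @param ... unused.
#' @return Tibble with parameter, slope, intercept, r-squared, n.
#' @export
glance.vr_regression <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, slope = x$slope, slope_stderr = x$slope_stderr,
    intercept = x$intercept, intercept_stderr = x$intercept_stderr,
    r_squared = x$r_squared, n_points = x$n_points
  )
}

#' Extrapolate a parameter to infinite bleach radius
#'
#' The regression intercept at 1/R = 0 is the finite-size-corrected
#' estimate of the parameter: at infinite radius the observation window no
#' longer truncates the walk, so the intercept recovers the true value.
#'
#' @param regression a [regress_vs_inverse_radius()] result.
#' @param level confidence level for the interval (default 0.95).
#' @return One-row tibble: `parameter`, `estimate` (the intercept),
#'   `std_error`, `conf_low`, `conf_high`.
#' @export
extrapolate_parameter <- function(regression, level = 0.95) {
  stopifnot(inherits(regression, "vr_regression"))
  tq <- qt(1 - (1 - level) / 2, df = regression$n_points - 2)
  tibble::tibble(
    parameter = regression$parameter,
    estimate = regression$intercept,
    std_error = regression$intercept_stderr,
    conf_low = regression$intercept - tq * regression$intercept_stderr,
    conf_high = regression$intercept + tq * regression$intercept_stderr
  )
}

#' Classify the motion from variable-radius slopes
#'
#' The slope signs discriminate the generative models: CTRW subdiffusion
#' pushes the fitted anomaly exponent *down* at small radii (negative
#' alpha-vs-1/R slope), whereas domain confinement pushes the apparent
#' mobile fraction *up* at small radii (positive M-vs-1/R slope, the
#' confinement diffusion law). A slope is called significant when
#' |slope| > z * stderr.
#'
#' @param alpha_regression `vr_regression` of `alpha` (aDm fits), or NULL.
#' @param m_regression `vr_regression` of `M` (rBm fits), or NULL.
#' @param z significance multiple (default 2).
#' @param unity_tol tolerance for "extrapolates to 1" in the Brownian
#'   call (default 0.05).
#' @return Character label, one of `"ctrw_like"`, `"domain_confined"`,
#'   `"brownian"`, `"inconclusive"`, with an `evidence` attribute tibble.
#' @export
classify_motion <- function(alpha_regression = NULL, m_regression = NULL,
                            z = 2, unity_tol = 0.05) {
  sig <- function(reg) {
    if (is.null(reg)) return(0)
    if (abs(reg$slope) > z * reg$slope_stderr) sign(reg$slope) else 0
  }
  a_sig <- sig(alpha_regression)
  m_sig <- sig(m_regression)
  a_int <- if (!is.null(alpha_regression)) alpha_regression$intercept else NA_real_
  m_int <- if (!is.null(m_regression)) m_regression$intercept else NA_real_

  label <- if (a_sig < 0) {
    "ctrw_like"
  } else if (a_sig > 0 || m_sig > 0) {
    "domain_confined"
  } else if (a_sig == 0 && m_sig == 0 &&
             ((!is.na(a_int) && abs(a_int - 1) <= unity_tol) ||
              (!is.na(m_int) && abs(m_int - 1) <= unity_tol))) {
    "brownian"
  } else {
    "inconclusive"
  }
  attr(label, "evidence") <- tibble::tibble(
    parameter = c("alpha", "M"),
    slope = c(
      if (is.null(alpha_regression)) NA_real_ else alpha_regression$slope,
      if (is.null(m_regression)) NA_real_ else m_regression$slope
    ),
    slope_sig = c(a_sig, m_sig),
    intercept = c(a_int, m_int)
  )
  label
}

#' Confinement-domain size from the mobile-fraction diffusion law
#'
#' The empirical confinement law \eqn{M = M_p + 0.63\, L / R} (valid for
#' L < R) links the apparent mobile fraction at bleach radius R to the
#' free (plateau) fraction \eqn{M_p} and the trapping-domain radius L.
#' Inverting the M-vs-1/R regression: `L = slope / 0.63`, `Mp =
#' intercept` (clipped to \[0, 1\]), confined fraction `1 - Mp`.
#'
#' @param m_regression a `vr_regression` with `parameter == "M"`.
#' @return One-row tibble of class `domain_estimate`: `L`, `Mp`,
#'   `confined_fraction`, `valid` (FALSE when the slope is negative or
#'   L >= the smallest radius used, where the law does not apply).
#' @export
#' @examples
#' s <- tibble::tibble(bleach_radius = c(0.32, 0.37, 0.44, 0.74), term = "M",
#'                     estimate = 0.80 + 0.063 / bleach_radius)
#' schram_domain_size(regress_vs_inverse_radius(s, "M"))
schram_domain_size <- function(m_regression) {
  stopifnot(inherits(m_regression, "vr_regression"))
  if (m_regression$parameter != "M") {
    abort("`m_regression` must regress the mobile fraction `M`.")
  }
  L <- m_regression$slope / 0.63
  Mp <- min(max(m_regression$intercept, 0), 1)
  r_smallest <- min(m_regression$radii)
  out <- tibble::tibble(
    L = L, L_stderr = m_regression$slope_stderr / 0.63,
    Mp = Mp, Mp_stderr = m_regression$intercept_stderr,
    confined_fraction = 1 - Mp,
    valid = m_regression$slope >= 0 && L < r_smallest
  )
  class(out) <- c("domain_estimate", class(out))
  out
}

#' Radius at which the fitted anomaly exponent reaches 1
#'
#' Solves `intercept + slope / R = 1` for R on the alpha-vs-1/R line: the
#' length scale where apparent subdiffusion crosses over to normal
#' diffusion. Only meaningful when the line actually crosses 1 at a
#' positive radius; otherwise the result is flagged.
#'
#' @param alpha_regression a `vr_regression` of `alpha`.
#' @return One-row tibble: `crossover_radius` (Inf when the intercept is
#'   exactly 1, NA when no positive-R crossover exists), `valid`.
#' @export
alpha_crossover_radius <- function(alpha_regression) {
  stopifnot(inherits(alpha_regression, "vr_regression"))
  b <- alpha_regression$intercept
  a <- alpha_regression$slope
  if (a == 0) {
    return(tibble::tibble(crossover_radius = NA_real_, valid = FALSE))
  }
  if (b == 1) {
    return(tibble::tibble(crossover_radius = Inf, valid = TRUE))
  }
  x <- (1 - b) / a  # crossing in 1/R
  if (x <= 0) {
    tibble::tibble(crossover_radius = NA_real_, valid = FALSE)
  } else {
    tibble::tibble(crossover_radius = 1 / x, valid = TRUE)
  }
}
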