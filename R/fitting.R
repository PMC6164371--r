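#' Fitting options
#'
#' @param init optional named starting values (overrides [initial_guess()]).
#' @param lower,upper optional named bounds; defaults enforce K in
#'   \[0, 30\], D and D_alpha >= 0, alpha in (0, 1\], M in \[0, 1\].
#' @param noise_sd per-point intensity sigma used to weight the
#'   chi-square; when `NULL` it is taken from the curve metadata if
#'   present, else estimated as the residual sd of an unweighted pilot fit.
#' @param n_starts number of deterministic multi-starts around the initial
#'   guess (guards against the shallow alpha–D_alpha trade-off).
#' @param max_iterations,tolerance optimizer controls (Levenberg–Marquardt
#'   trust region, [minpack.lm::nls.lm()]).
#' @param n_terms series truncation for the model evaluations.
#' @return List of class `fit_options`.
#' @export
fit_options <- function(init = NULL, lower = NULL, upper = NULL,
                        noise_sd = NULL, n_starts = 3,
                        max_iterations = 200, tolerance = 1e-10,
                        n_terms = 19) {
  structure(
    list(init = init, lower = lower, upper = upper, noise_sd = noise_sd,
         n_starts = n_starts, max_iterations = max_iterations,
         tolerance = tolerance, n_terms = n_terms),
    class = "fit_options"
  )
}

default_bounds <- function(model_key) {
  lower <- c(K = 1e-4, D_alpha = 1e-8, D = 1e-8, alpha = 0.02, M = 0)
  upper <- c(K = 30, D_alpha = 1e6, D = 1e6, alpha = 1, M = 1)
  p <- model_params(model_key)
  list(lower = lower[p], upper = upper[p])
}

#' Starting values for a recovery fit
#'
#' K is obtained by numerically inverting the model's t = 0 bleach depth;
#' the diffusion scale from the empirical half-recovery time via
#' \eqn{\tau_{1/2} \approx R^2 / (4D)}; alpha starts at 0.8 and M at 0.9.
#' A curve that never dips below ~1 is flagged degenerate and gets
#' conservative defaults.
#'
#' @param curve a [frap_curve()] with >= 10 points.
#' @param model_key `"adm"`, `"bm"` or `"rbm"`.
#' @param n_terms series truncation used when inverting the depth.
#' @return Named numeric vector of starting values; attribute
#'   `degenerate` is TRUE for flat curves.
#' @export
initial_guess <- function(curve, model_key, n_terms = 19) {
  model_key <- match.arg(model_key, c("adm", "bm", "rbm"))
  if (nrow(curve) < 10) abort("need at least 10 curve points for a guess.")
  R <- curve_meta(curve)$bleach_radius
  if (is.na(R)) abort("curve has no bleach radius `R`; supply one before fitting.")
  I0 <- curve$intensity[1]
  Iend <- mean(tail(curve$intensity, max(3, nrow(curve) %/% 20)))
  degenerate <- I0 > 0.98 || Iend <= I0 + 1e-3

  K <- if (degenerate) 0.5 else invert_depth(min(I0, 0.995), model_key, n_terms)
  t_half <- if (degenerate) {
    median(curve$time)
  } else {
    half <- I0 + 0.5 * (Iend - I0)
    curve$time[which(curve$intensity >= half)[1]]
  }
  if (is.na(t_half) || t_half <= 0) t_half <- median(curve$time)
  D <- R^2 / (4 * t_half)

  guess <- switch(model_key,
    adm = c(K = K, D_alpha = R^2 / (4 * t_half^0.8), alpha = 0.8),
    bm = c(K = K, D = D),
    rbm = c(K = K, D = D, M = 0.9)
  )
  b <- default_bounds(model_key)
  guess <- pmin(pmax(guess, b$lower), b$upper)
  attr(guess, "degenerate") <- degenerate
  guess
}

# solve model(t = 0) = depth for K on [1e-4, 30]
invert_depth <- function(depth, model_key, n_terms = 19) {
  st <- series_settings(n_terms, convergence_guard = Inf)
  f <- function(K) {
    v <- switch(model_key,
      adm = adm_recovery(0, 1, 0, 0.8, K, st),
      bm = ,
      rbm = (1 - exp(-K)) / K
    )
    as.numeric(v) - depth
  }
  lo <- 1e-4; hi <- 30
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Fit a recovery curve with a registered model
#'
#' Bounded Levenberg–Marquardt least squares on the weighted residuals
#' \eqn{(I_{model}(t_i) - I_i)/\sigma_i}, with deterministic multi-starts
#' around [initial_guess()]. Standard errors come from the local
#' curvature (J'J) of the objective at the optimum. Non-convergence never
#' raises: the result carries `converged = FALSE`.
#'
#' @param curve a [frap_curve()].
#' @param model_key `"adm"`, `"bm"` or `"rbm"`.
#' @param options a [fit_options()].
#' @return An object of class `frap_fit`: model key, estimates with
#'   standard errors (as a tibble), chi-square and reduced chi-square,
#'   residuals, convergence flag, the sigma used and its provenance, and
#'   for `adm` fits the derived Brownian-equivalent `D` from the
#'   dispersion relation.
#' @export
#' @examples
#' tg <- 10^seq(-1, 2, length.out = 60)
#' cv <- frap_curve(tg, bm_recovery(tg, 1, D = 0.5, K = 1), bleach_radius = 1)
#' fit <- fit_recovery(cv, "bm")
#' tidy(fit)
fit_recovery <- function(curve, model_key, options = fit_options()) {
  model_key <- match.arg(model_key, c("adm", "bm", "rbm"))
  R <- curve_meta(curve)$bleach_radius
  if (is.na(R)) abort("curve has no bleach radius `R`; supply one before fitting.")
  st <- series_settings(options$n_terms, convergence_guard = Inf)
  b <- default_bounds(model_key)
  lower <- replace_named(b$lower, options$lower)
  upper <- replace_named(b$upper, options$upper)

  guess <- if (is.null(options$init)) {
    initial_guess(curve, model_key, options$n_terms)
  } else {
    g <- unlist(options$init)[model_params(model_key)]
    if (anyNA(g)) abort("`init` must name every model parameter.")
    g
  }

  # sigma for the weighted objective
  sigma_source <- "supplied"
  sigma <- options$noise_sd
  if (is.null(sigma)) {
    m_sd <- curve_meta(curve)$noise_sd
    if (!is.na(m_sd) && m_sd > 0) {
      sigma <- m_sd
      sigma_source <- "curve metadata"
    }
  }
  pilot <- NULL
  if (is.null(sigma)) {
    pilot <- lm_fit_once(curve, model_key, guess, lower, upper, 1, st, options)
    rsd <- sd(pilot$residuals)
    sigma <- if (is.finite(rsd) && rsd > 1e-8) rsd else 1
    sigma_source <- "pilot-fit residual sd"
  }

  # deterministic multi-starts: the guess plus fixed perturbations
  starts <- list(guess)
  if (options$n_starts >= 2) {
    s2 <- guess
    if ("alpha" %in% names(s2)) s2[["alpha"]] <- 0.6
    s2[scale_par(model_key)] <- s2[[scale_par(model_key)]] * 3
    starts <- c(starts, list(pmin(pmax(s2, lower), upper)))
  }
  if (options$n_starts >= 3) {
    s3 <- guess
    if ("alpha" %in% names(s3)) s3[["alpha"]] <- 0.95
    s3[scale_par(model_key)] <- s3[[scale_par(model_key)]] / 3
    starts <- c(starts, list(pmin(pmax(s3, lower), upper)))
  }

  fits <- lapply(starts, function(s) {
    lm_fit_once(curve, model_key, s, lower, upper, sigma, st, options)
  })
  ok <- vapply(fits, function(f) f$converged, TRUE)
  pool <- if (any(ok)) fits[ok] else fits
  chis <- vapply(pool, function(f) f$chi2, 0)
  best_chi <- min(chis)
  cand <- which(chis <= best_chi * (1 + 1e-6))
  if (length(cand) > 1 && "alpha" %in% names(guess)) {
    alphas <- vapply(pool[cand], function(f) f$par[["alpha"]], 0)
    best <- cand[which.min(alphas)]  # ties broken toward lower alpha
  } else {
    best <- cand[1]
  }
  f <- pool[[best]]

  se <- curvature_se(curve, model_key, f$par, sigma, st)
  n <- nrow(curve)
  p <- length(f$par)
  # estimates pinned to a box bound are censored, not interior optima
  at_bound <- abs(f$par - lower) < 1e-8 * (1 + abs(lower)) |
    abs(f$par - upper) < 1e-8 * (1 + abs(upper))
  est <- tibble::tibble(term = names(f$par), estimate = unname(f$par),
                        std_error = se, at_bound = unname(at_bound))
  if (model_key == "adm") {
    a <- f$par[["alpha"]]
    D <- if (a < 1 - 1e-9) alpha_to_diffusion(f$par[["D_alpha"]], a) else NA_real_
    # first-order propagation through the dispersion relation at fixed alpha
    D_se <- if (!is.na(D) && f$par[["D_alpha"]] > 0) {
      D * se[est$term == "D_alpha"] / f$par[["D_alpha"]]
    } else {
      NA_real_
    }
    est <- dplyr::bind_rows(
      est, tibble::tibble(term = "D", estimate = D, std_error = D_se,
                          at_bound = any(at_bound[c("D_alpha", "alpha")]))
    )
  }

  structure(
    list(
      model_key = model_key, estimates = est, par = f$par,
      chi2 = f$chi2, chi2_reduced = f$chi2 / (n - p),
      df = n - p, residuals = f$residuals, fitted = f$fitted,
      converged = f$converged, n_terms = options$n_terms,
      bleach_radius = R, sigma = sigma, sigma_source = sigma_source,
      n_points = n, curve = curve
    ),
    class = "frap_fit"
  )
}

scale_par <- function(model_key) if (model_key == "adm") "D_alpha" else "D"

replace_named <- function(base, override) {
  if (is.null(override)) return(base)
  override <- unlist(override)
  base[intersect(names(override), names(base))] <-
    override[intersect(names(override), names(base))]
  base
}

lm_fit_once <- function(curve, model_key, start, lower, upper, sigma, st,
                        options) {
  R <- curve_meta(curve)$bleach_radius
  resid_fn <- function(p) {
    p <- setNames(as.numeric(p), names(start))
    v <- tryCatch(
      as.numeric(frap_model(model_key, curve$time, R, as.list(p), st)),
      error = function(e) rep(NA_real_, nrow(curve))
    )
    r <- (v - curve$intensity) / sigma
    r[!is.finite(r)] <- 1e6
    r
  }
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iterations, ftol = options$tolerance,
        ptol = options$tolerance
      )
    ),
    error = function(e) NULL
  )
  if (is.null(out)) {
    return(list(par = start, chi2 = sum(resid_fn(start)^2),
                residuals = resid_fn(start) * sigma,
                fitted = curve$intensity + resid_fn(start) * sigma,
                converged = FALSE))
  }
  par <- setNames(as.numeric(out$par), names(start))
  res <- resid_fn(par)
  list(
    par = par, chi2 = sum(res^2), residuals = res * sigma,
    fitted = curve$intensity + res * sigma,
    converged = out$info %in% 1:4
  )
}

# standard errors from the numerical Jacobian at the optimum:
# cov = s^2 (J'J)^{-1} on the sigma-weighted residuals
curvature_se <- function(curve, model_key, par, sigma, st) {
  R <- curve_meta(curve)$bleach_radius
  f <- function(p) {
    as.numeric(frap_model(model_key, curve$time, R,
                          as.list(setNames(p, names(par))), st)) / sigma
  }
  J <- tryCatch({
    base <- f(par)
    sapply(seq_along(par), function(j) {
      h <- max(abs(par[j]) * 1e-6, 1e-10)
      pj <- par
      pj[j] <- pj[j] + h
      (f(pj) - base) / h
    })
  }, error = function(e) NULL)
  n <- nrow(curve)
  p <- length(par)
  if (is.null(J)) return(rep(NA_real_, p))
  res <- f(par) - curve$intensity / sigma
  s2 <- sum(res^2) / max(n - p, 1)
  cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cv)) rep(NA_real_, p) else sqrt(pmax(diag(cv), 0))
}

#' Chi-square goodness of fit for given parameters
#'
#' \eqn{\chi^2 = \sum_i (I_{model}(t_i) - I_i)^2 / \sigma^2}; the reduced
#' form divides by (points - free parameters).
#'
#' @param curve a [frap_curve()].
#' @param model_key `"adm"`, `"bm"` or `"rbm"`.
#' @param params named parameter list for the model.
#' @param noise_sd per-point sigma (> 0).
#' @param n_terms series truncation.
#' @return Tibble with `chi2` and `chi2_reduced`.
#' @export
chi_square <- function(curve, model_key, params, noise_sd, n_terms = 19) {
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  p <- length(model_params(model_key))
  if (nrow(curve) <= p) abort("fewer points than free parameters.")
  R <- curve_meta(curve)$bleach_radius
  st <- series_settings(n_terms, convergence_guard = Inf)
  v <- as.numeric(frap_model(model_key, curve$time, R, params, st))
  chi2 <- sum(((v - curve$intensity) / noise_sd)^2)
  tibble::tibble(chi2 = chi2, chi2_reduced = chi2 / (nrow(curve) - p))
}

#' Fit all three models and rank them
#'
#' Fits `adm`, `bm` and `rbm` to the same curve and ranks the converged
#' fits by reduced chi-square (ascending). All three fits share the same
#' sigma so the chi-squares are comparable.
#'
#' @param curve a [frap_curve()].
#' @param options a [fit_options()].
#' @return Tibble, one row per model, ordered best-first, with columns
#'   `model`, `rank`, `converged`, `chi2`, `chi2_reduced` and a `fit`
#'   list-column holding the full `frap_fit` objects (residual traces for
#'   linear and log–log inspection included).
#' @export
compare_models <- function(curve, options = fit_options()) {
  # one shared sigma across models for a comparable chi-square
  if (is.null(options$noise_sd)) {
    pilot <- fit_recovery(curve, "rbm", options)
    options$noise_sd <- pilot$sigma
  }
  fits <- lapply(c("adm", "bm", "rbm"), function(k) {
    fit_recovery(curve, k, options)
  })
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$model_key, ""),
    converged = vapply(fits, function(f) f$converged, TRUE),
    chi2 = vapply(fits, function(f) f$chi2, 0),
    chi2_reduced = vapply(fits, function(f) f$chi2_reduced, 0),
    fit = fits
  )
  out <- dplyr::arrange(out, !.data$converged, .data$chi2_reduced)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "model", "rank")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit: %s> R = %g, chi2 = %.4g (reduced %.4g), converged: %s\n",
    x$model_key, x$bleach_radius, x$chi2, x$chi2_reduced, x$converged
  ))
  print(x$estimates)
  invisible(x)
}

#' Tidy a recovery fit
#' @param x a `frap_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @export
tidy.frap_fit <- function(x, ...) x$estimates

#' One-row fit summary
#' @param x a `frap_fit`.
#' @param ... unused.
#' @return Tibble with model key, chi-squares, df, convergence, sigma.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_key, bleach_radius = x$bleach_radius,
    chi2 = x$chi2, chi2_reduced = x$chi2_reduced, df = x$df,
    converged = x$converged, sigma = x$sigma, sigma_source = x$sigma_source,
    n_points = x$n_points
  )
}

#' @export
fitted.frap_fit <- function(object, ...) object$fitted

#' @export
residuals.frap_fit <- function(object, ...) object$residuals

#' Extract a fitted parameter
#' @param fit a `frap_fit`.
#' @param term parameter name (e.g. `"alpha"`, `"D"`, `"M"`).
#' @return Estimate, or `NA` if absent.
#' @export
fit_param <- function(fit, term) {
  i <- match(term, fit$estimates$term)
  if (is.na(i)) NA_real_ else fit$estimates$estimate[i]
}
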