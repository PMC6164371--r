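#' Confocal acquisition protocol
#'
#' The acquisition protocol of the emulated instrument: 150 samples over
#' 100 s, spaced 0.44 s early in the recovery and ~1 s later on (denser
#' sampling early, where the recovery is fast, while avoiding monitoring
#' photobleach late); the 0.2 s bleach pulse is metadata only.
#'
#' @param total_duration seconds (default 100).
#' @param n_points samples (default 150).
#' @param early_interval early frame spacing, s (default 0.44).
#' @param late_interval late frame spacing, s (default 1.0).
#' @param bleach_pulse bleach pulse length, s (metadata; default 0.2).
#' @return List of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(total_duration = 100, n_points = 150,
                                 early_interval = 0.44, late_interval = 1.0,
                                 bleach_pulse = 0.2) {
  if (early_interval <= 0 || late_interval <= 0) {
    abort("intervals must be > 0.")
  }
  structure(
    list(total_duration = total_duration, n_points = n_points,
         early_interval = early_interval, late_interval = late_interval,
         bleach_pulse = bleach_pulse),
    class = "acquisition_protocol"
  )
}

#' Dual-rate observation time grid
#'
#' Builds the strictly increasing grid implied by the protocol: `n_early`
#' points at the early spacing then `n_late` points at (approximately) the
#' late spacing, with the counts solved from `n_early + n_late = n_points`
#' and `n_early * early + n_late * late = total_duration` (rounded to
#' integers) and the late block rescaled so the final point lands exactly
#' on `total_duration`. The default protocol gives 89 points at 0.44 s
#' starting at t = 0 (the frame taken immediately after the bleach pulse)
#' then 61 points at ~1 s, 150 points ending at 100 s.
#'
#' @param protocol an [acquisition_protocol()].
#' @return Numeric vector of `n_points` strictly increasing times.
#' @export
experimental_time_grid <- function(protocol = acquisition_protocol()) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  de <- protocol$early_interval
  dl <- protocol$late_interval
  N <- protocol$n_points
  Ttot <- protocol$total_duration
  # n_early * de + n_late * dl = Ttot, n_early + n_late = N
  n_early <- round((N * dl - Ttot) / (dl - de))
  n_late <- N - n_early
  if (n_early < 1 || n_late < 1) {
    abort("protocol inconsistent: no early/late split satisfies the counts.")
  }
  # first frame immediately post-bleach (t = 0) anchors the bleach depth
  t_switch <- (n_early - 1) * de
  if (t_switch >= Ttot) abort("protocol inconsistent: early block overruns the duration.")
  early <- de * (seq_len(n_early) - 1)
  late <- t_switch + (Ttot - t_switch) * seq_len(n_late) / n_late
  grid <- c(early, late)
  if (any(diff(grid) <= 0)) abort("protocol inconsistent: grid not increasing.")
  grid
}

#' Instrument table of bleach radii and waists
#'
#' The per-objective calibration of the emulated confocal instrument:
#' measured bleach-disk radius R (with uncertainty) and laser waist for
#' the four objectives. Every row satisfies R ~ 2 x waist.
#'
#' @return Tibble with columns `objective`, `magnification`, `na`,
#'   `bleach_radius_um`, `radius_sd_um`, `waist_nm`.
#' @export
instrument_table <- function() {
  tibble::tibble(
    objective = c("16x", "40x", "63x", "100x"),
    magnification = c(16, 40, 63, 100),
    na = c(1.0, 1.3, 1.4, 1.4),
    bleach_radius_um = c(0.74, 0.44, 0.37, 0.32),
    radius_sd_um = c(0.04, 0.03, 0.01, 0.01),
    waist_nm = c(370, 222, 185, 160)
  )
}

#' Generate one synthetic recovery curve from a model
#'
#' Evaluates a registered recovery model on the acquisition grid and adds
#' iid Gaussian noise, recording the generative truth in the curve
#' metadata so downstream recovery can be scored.
#'
#' @param model_key `"adm"`, `"bm"` or `"rbm"`.
#' @param params named truth parameters for the model.
#' @param R bleach radius (same length unit as `params`' D).
#' @param times observation times; defaults to
#'   [experimental_time_grid()].
#' @param noise_sd additive intensity noise sd (default 0.03,
#'   experiment-like scatter).
#' @param seed optional integer seed.
#' @param units unit labels (default micrometres/seconds).
#' @return A [frap_curve()] with provenance `"synthetic-model"`.
#' @export
generate_curve <- function(model_key, params, R,
                           times = experimental_time_grid(),
                           noise_sd = 0.03, seed = NULL,
                           units = frap_units("um", "s")) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  v <- as.numeric(frap_model(model_key, times, R, params))
  if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
  frap_curve(
    times, v, bleach_radius = R, bleach_constant = params$K,
    noise_sd = noise_sd, provenance = "synthetic-model", units = units,
    truth = c(params, list(model = model_key)),
    seed = seed %||% NA_integer_
  )
}

#' Generate a variable-radius FRAP dataset
#'
#' The synthetic twin of a variable-radius cell experiment: replicate
#' recovery curves at each bleach radius, generated either from a
#' closed-form model (`"adm"`, `"bm"`, `"rbm"`) or from the Monte-Carlo
#' walk (`"ctrw-sim"`). For `rbm` truth with confinement parameters
#' (`Mp`, `L`), the mobile fraction at each radius follows the
#' confinement law `M(R) = Mp + 0.63 * L / R`; when `L >= min(radii)` the
#' dataset is still generated but flagged, since the law only holds for
#' L < R.
#'
#' @param model_key `"adm"`, `"bm"`, `"rbm"` or `"ctrw-sim"`.
#' @param params truth parameters. For `rbm` either a fixed `M` or
#'   confinement truth `Mp` and `L`; for `ctrw-sim` the [ctrw_config()]
#'   fields (`alpha`, `D`, `K`, `n_particles`, `domain_radius`, ...).
#' @param radii bleach radii; defaults to the instrument table radii.
#' @param replicates_per_radius independent curves per radius.
#' @param noise_sd additive intensity noise (default 0.03).
#' @param times observation grid; defaults to [experimental_time_grid()]
#'   for model curves and the [ctrw_config()] default for `ctrw-sim`.
#' @param seed integer seed for the whole dataset; per-curve randomness is
#'   drawn from the one seeded stream in a fixed order.
#' @param units unit labels.
#' @return Tibble with one row per curve: `curve_id`, `bleach_radius`,
#'   `replicate`, `curve` (list-column of [frap_curve()]); attribute
#'   `truth` records the generative spec, attribute `confinement_valid`
#'   flags the L < min(R) condition for confinement truth.
#' @export
generate_vrfrap_dataset <- function(model_key, params,
                                    radii = instrument_table()$bleach_radius_um,
                                    replicates_per_radius = 3,
                                    noise_sd = 0.03, times = NULL,
                                    seed = NULL,
                                    units = frap_units("um", "s")) {
  model_key <- match.arg(model_key, c("adm", "bm", "rbm", "ctrw-sim"))
  if (replicates_per_radius < 1) abort("`replicates_per_radius` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  params <- as.list(params)

  confinement <- model_key == "rbm" && all(c("Mp", "L") %in% names(params))
  confinement_valid <- TRUE
  if (confinement && params$L >= min(radii)) {
    confinement_valid <- FALSE
    warn(sprintf(
      "confinement law requires L < R: L = %g >= smallest radius %g; dataset flagged.",
      params$L, min(radii)
    ))
  }

  grid <- expand.grid(replicate = seq_len(replicates_per_radius),
                      bleach_radius = radii)
  rows <- purrr::pmap(grid, function(replicate, bleach_radius) {
    if (model_key == "ctrw-sim") {
      cfg_args <- params[intersect(names(params), names(formals(ctrw_config)))]
      cfg_args$bleach_radius <- bleach_radius
      if (!is.null(times)) cfg_args$observation_times <- times
      cfg_args$seed <- NULL  # one stream for the whole dataset
      cv <- simulate_recovery(do.call(ctrw_config, cfg_args))
      if (noise_sd > 0) {
        cv$intensity <- cv$intensity + rnorm(nrow(cv), sd = noise_sd)
        attr(cv, "meta")$noise_sd <- noise_sd
      }
      attr(cv, "meta")$units <- units
    } else {
      p <- params
      if (confinement) {
        p$M <- min(params$Mp + 0.63 * params$L / bleach_radius, 1)
        p$Mp <- NULL
        p$L <- NULL
      }
      cv <- generate_curve(
        model_key, p, bleach_radius,
        times = times %||% experimental_time_grid(),
        noise_sd = noise_sd, seed = NULL, units = units
      )
    }
    tibble::tibble(bleach_radius = bleach_radius, replicate = replicate,
                   curve = list(cv))
  })
  out <- dplyr::bind_rows(rows)
  out$curve_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "curve_id")
  attr(out, "truth") <- c(params, list(model = model_key, seed = seed,
                                       noise_sd = noise_sd))
  attr(out, "confinement_valid") <- confinement_valid
  out
}
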