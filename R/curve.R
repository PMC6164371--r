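#' Construct a FRAP recovery curve
#'
#' A `frap_curve` is a tibble with columns `time` and `intensity`
#' (normalised so the prebleach level is 1) plus metadata attributes:
#' the bleach radius `R`, the laser waist `w`, the bleach constant `K`
#' (when known), units, noise level, provenance and, for synthetic
#' curves, the generative truth.
#'
#' @param time strictly increasing observation times.
#' @param intensity normalised fluorescence at each time.
#' @param bleach_radius bleach/readout disk radius R (same length unit as
#'   `waist`).
#' @param waist laser waist w; defaults to `bleach_radius` (the
#'   parameterisation used by the recovery models).
#' @param bleach_constant photobleaching constant K, if known.
#' @param noise_sd additive noise level on intensity, if known.
#' @param provenance one of `"simulated"`, `"synthetic-model"`, `"file"`.
#' @param units length/time unit labels, e.g. `c(length = "au", time = "au")`.
#' @param truth optional named list of generative parameters.
#' @param seed integer seed the curve was generated from, if any.
#'
#' @return A tibble of class `frap_curve`.
#' @export
#' @examples
#' tg <- experimental_time_grid()
#' frap_curve(tg, rep(1, length(tg)), bleach_radius = 0.37, units = frap_units("um", "s"))
frap_curve <- function(time, intensity, bleach_radius = NA_real_,
                       waist = NULL, bleach_constant = NA_real_,
                       noise_sd = NA_real_,
                       provenance = c("synthetic-model", "simulated", "file"),
                       units = frap_units(), truth = NULL, seed = NA_integer_) {
  provenance <- match.arg(provenance)
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) {
    abort("`time` and `intensity` must have the same length.")
  }
  if (length(time) && any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  if (any(!is.finite(intensity))) {
    abort("`intensity` must be finite.")
  }
  out <- tibble::tibble(time = time, intensity = intensity)
  class(out) <- c("frap_curve", class(out))
  attr(out, "meta") <- list(
    bleach_radius = as.numeric(bleach_radius),
    waist = as.numeric(waist %||% bleach_radius),
    bleach_constant = as.numeric(bleach_constant),
    noise_sd = as.numeric(noise_sd),
    provenance = provenance,
    units = units,
    truth = truth,
    seed = seed
  )
  out
}

#' Unit labels for a curve
#'
#' @param length,time unit labels ("au" for simulation arbitrary units,
#'   "um"/"s" for instrument data).
#' @return Named character vector.
#' @export
frap_units <- function(length = "au", time = "au") {
  c(length = length, time = time)
}

#' Curve metadata
#'
#' @param curve a [frap_curve()].
#' @return Named list of metadata (bleach radius, waist, K, units, ...).
#' @export
curve_meta <- function(curve) {
  m <- attr(curve, "meta", exact = TRUE)
  if (is.null(m)) abort("not a `frap_curve`: metadata missing.")
  m
}

#' @export
print.frap_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf(
    "<frap_curve> %d points, R = %s %s, provenance = %s\n",
    nrow(x), format(m$bleach_radius), m$units[["length"]], m$provenance
  ))
  NextMethod()
}

# metadata keys persisted in the file header, in a fixed order
.curve_meta_keys <- c(
  "bleach_radius", "waist", "bleach_constant", "noise_sd",
  "provenance", "length_unit", "time_unit", "seed"
)

#' Write a recovery curve to delimited text
#'
#' The on-disk dialect is comma-separated UTF-8 with `.` decimal separator:
#' `# key=value` metadata comment lines, a `time,intensity` header, then the
#' data at full double precision so a write/read round trip is bit-exact.
#'
#' @param curve a [frap_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frap_curve <- function(curve, path) {
  m <- curve_meta(curve)
  vals <- list(
    bleach_radius = m$bleach_radius, waist = m$waist,
    bleach_constant = m$bleach_constant, noise_sd = m$noise_sd,
    provenance = m$provenance,
    length_unit = m$units[["length"]], time_unit = m$units[["time"]],
    seed = m$seed
  )
  hdr <- character(0)
  for (k in .curve_meta_keys) {
    v <- vals[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    hdr <- c(hdr, sprintf("# %s=%s", k, v))
  }
  if (!is.null(m$truth)) {
    for (nm in names(m$truth)) {
      v <- m$truth[[nm]]
      v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      hdr <- c(hdr, sprintf("# truth_%s=%s", nm, v))
    }
  }
  body <- sprintf("%.17g,%.17g", curve$time, curve$intensity)
  writeLines(c(hdr, "time,intensity", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a recovery curve from delimited text
#'
#' Inverse of [write_frap_curve()]. Metadata lines are `# key=value`; the
#' bleach radius may be absent, in which case downstream fitting refuses
#' until one is supplied.
#'
#' @param path file in the documented CSV dialect.
#' @return A [frap_curve()] with `provenance = "file"`.
#' @export
read_frap_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  kv <- strsplit(meta_raw, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) {
    abort(sprintf(
      "unparseable metadata at line %d of '%s': '%s'",
      which(is_meta)[bad[1]], path, lines[is_meta][bad[1]]
    ))
  }
  meta <- setNames(
    vapply(kv, function(p) trimws(p[2]), ""),
    vapply(kv, function(p) trimws(p[1]), "")
  )

  body <- lines[!is_meta]
  if (!length(body)) abort(sprintf("'%s': no data lines found.", path))
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  ti <- match(c("time", "intensity"), trimws(header))
  if (anyNA(ti)) {
    abort(sprintf(
      "'%s': header line %d must contain columns `time` and `intensity`.",
      path, which(!is_meta)[1]
    ))
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  short <- which(lengths(rows) < max(ti))
  if (length(short)) {
    abort(sprintf(
      "'%s': malformed data row at line %d.",
      path, which(!is_meta)[short[1] + 1]
    ))
  }
  time <- as.numeric(vapply(rows, `[`, "", ti[1]))
  intensity <- as.numeric(vapply(rows, `[`, "", ti[2]))
  nonmono <- which(diff(time) <= 0)
  if (length(nonmono)) {
    abort(sprintf(
      "'%s': times not strictly increasing at line %d.",
      path, which(!is_meta)[nonmono[1] + 2]
    ))
  }

  num <- function(key) {
    if (key %in% names(meta)) as.numeric(meta[[key]]) else NA_real_
  }
  chr <- function(key, default) {
    if (key %in% names(meta)) meta[[key]] else default
  }
  truth_keys <- grep("^truth_", names(meta), value = TRUE)
  truth <- if (length(truth_keys)) {
    setNames(
      lapply(truth_keys, function(k) {
        x <- meta[[k]]
        n <- suppressWarnings(as.numeric(x))
        if (is.na(n)) x else n
      }),
      sub("^truth_", "", truth_keys)
    )
  } else {
    NULL
  }
  curve <- frap_curve(
    time, intensity,
    bleach_radius = num("bleach_radius"),
    waist = if ("waist" %in% names(meta)) num("waist") else NULL,
    bleach_constant = num("bleach_constant"),
    noise_sd = num("noise_sd"),
    provenance = "file",
    units = frap_units(
      length = chr("length_unit", "au"),
      time = chr("time_unit", "au")
    ),
    truth = truth,
    seed = as.integer(num("seed"))
  )
  attr(curve, "meta")$source_path <- path
  curve
}
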