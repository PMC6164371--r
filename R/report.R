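REPORT_SCHEMA_VERSION <- "1.0"

#' Write a structured JSON analysis report
#'
#' Serialises fit or variable-radius results to JSON with a fixed key
#' order: schema version, tool version, seed, input file checksums (md5,
#' when the results reference files on disk), then the payload. Two runs
#' with the same seed produce byte-identical reports apart from the
#' `timestamp` field.
#'
#' @param results a `frap_fit`, a [compare_models()] table, or a named
#'   list of tidy components (e.g. regressions, classification, domain
#'   estimate).
#' @param path output path.
#' @param seed optional integer seed to record.
#' @param inputs optional character vector of input file paths to
#'   checksum.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, inputs = NULL) {
  payload <- report_payload(results)
  checksums <- NULL
  if (!is.null(inputs)) {
    checksums <- as.list(tools::md5sum(inputs))
  }
  doc <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    tool = "vrfrap",
    tool_version = as.character(utils::packageVersion("vrfrap")),
    seed = seed,
    input_checksums = checksums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    results = payload
  )
  doc <- doc[!vapply(doc, is.null, TRUE)]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "frap_fit")) {
    return(list(
      type = "fit", model_key = x$model_key,
      bleach_radius = x$bleach_radius,
      params = setNames(as.list(x$estimates$estimate), x$estimates$term),
      stderr = setNames(as.list(x$estimates$std_error), x$estimates$term),
      chi2 = x$chi2, chi2_reduced = x$chi2_reduced, df = x$df,
      converged = x$converged, n_terms = x$n_terms,
      sigma = x$sigma, sigma_source = x$sigma_source
    ))
  }
  if (inherits(x, "vr_regression")) {
    return(c(list(type = "regression"), as.list(glance(x))))
  }
  if (is.data.frame(x)) {
    keep <- x[!vapply(x, is.list, TRUE)]
    return(list(type = "table", rows = keep))
  }
  if (is.list(x)) {
    return(lapply(x, report_payload))
  }
  x
}

#' Read back a JSON report
#'
#' @param path a file written by [write_report()].
#' @return Parsed list; errors when the schema version is missing.
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) {
    abort(sprintf("'%s' is not a vrfrap report: schema_version missing.", path))
  }
  doc
}
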