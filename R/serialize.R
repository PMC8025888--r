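# JSON round-trips for detection reports and calibrations.

.report_as_list <- function(x) {
  out <- unclass(x)
  out$rings <- if (!is.null(out$rings)) as.data.frame(out$rings)
  out$os_regions <- if (!is.null(out$os_regions)) as.data.frame(out$os_regions)
  out$stage2 <- if (!is.null(out$stage2)) as.data.frame(out$stage2)
  out
}

#' Write / read a detection report as JSON
#'
#' The JSON file carries every field of the report; reading it back yields
#' an identical `ice_report`.
#'
#' @param report An `ice_report`.
#' @param path File path.
#' @return `path` (write) or an `ice_report` (read).
#' @export
write_ice_report <- function(report, path) {
  jsonlite::write_json(.report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ice_report
#' @export
read_ice_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("rings", "os_regions", "stage2")) {
    if (!is.null(x[[nm]])) x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  if (!is.null(x$flags)) x$flags <- as.character(x$flags)
  structure(x, class = "ice_report")
}

#' Write / read a calibration as JSON
#'
#' @param calibration An `ice_calibration`.
#' @param path File path.
#' @return `path` (write) or an `ice_calibration` (read).
#' @export
write_ice_calibration <- function(calibration, path) {
  x <- unclass(calibration)
  x$gev_ics <- unclass(x$gev_ics)
  x$gev_os <- unclass(x$gev_os)
  x$stage2_quantiles <- as.data.frame(x$stage2_quantiles)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ice_calibration
#' @export
read_ice_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gev_ics <- structure(x$gev_ics, class = "gev_fit")
  x$gev_os <- structure(x$gev_os, class = "gev_fit")
  x$stage2_quantiles <- tibble::as_tibble(x$stage2_quantiles)
  x$flags <- as.character(x$flags %||% character())
  structure(x, class = "ice_calibration")
}
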