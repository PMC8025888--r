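# Tidiers: one-row-per-component summaries (tidy) and one-row-per-object
# summaries (glance) for the fitted/report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection report
#'
#' One row per scored ring with its windowed score maxima and ICS.
#'
#' @param x An `ice_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ice_report
#' @export
tidy.ice_report <- function(x, ...) {
  if (is.null(x$rings) || !nrow(x$rings)) return(tibble::tibble())
  out <- tibble::as_tibble(x$rings)
  out$stage <- "common"
  if (!is.null(x$stage2) && nrow(x$stage2)) {
    s2 <- tibble::as_tibble(x$stage2)
    s2$stage <- "hexagonal_only"
    out <- dplyr::bind_rows(out, s2)
  }
  out
}

#' @rdname tidy.ice_report
#' @method glance ice_report
#' @export
glance.ice_report <- function(x, ...) {
  tibble::tibble(
    classification = x$classification,
    combined_ics = x$combined_ics %||% NA_real_,
    p_ice = x$p_ice %||% NA_real_,
    os_max = x$os_max %||% NA_real_,
    p_obs = x$p_obs %||% NA_real_,
    n_reflections = x$n_reflections,
    d_min = x$d_min
  )
}

#' Tidy a calibration
#'
#' @param x An `ice_calibration`.
#' @param ... Unused.
#' @return Tidy: one row per null-distribution parameter set; glance: one
#'   row with weights and thresholds.
#' @method tidy ice_calibration
#' @export
tidy.ice_calibration <- function(x, ...) {
  tibble::tibble(
    statistic = c("combined_ics", "os_max"),
    loc = c(x$gev_ics$loc, x$gev_os$loc),
    scale = c(x$gev_ics$scale, x$gev_os$scale),
    shape = c(x$gev_ics$shape, x$gev_os$shape),
    method = c(x$gev_ics$method, x$gev_os$method)
  )
}

#' @rdname tidy.ice_calibration
#' @method glance ice_calibration
#' @export
glance.ice_calibration <- function(x, ...) {
  tibble::tibble(
    w_ifs = x$w_ifs, w_ds = x$w_ds,
    p_ice_threshold = x$p_ice_threshold,
    p_obs_threshold = x$p_obs_threshold,
    n_training = x$n_training, n_clean = x$n_clean
  )
}

#' Tidy a mixture fit
#'
#' @param x An `ice_mixture_fit`.
#' @param ... Unused.
#' @return Tidy: one row per fitted parameter; glance: one row with the
#'   cubic fraction and convergence.
#' @method tidy ice_mixture_fit
#' @export
tidy.ice_mixture_fit <- function(x, ...) {
  if (!is.null(x$flag) && identical(x$flag, "no ice signal")) {
    return(tibble::tibble())
  }
  tibble::tibble(
    term = c("hex_scale", "cubic_scale", "width_2theta", "cell_scale"),
    estimate = c(x$hex_scale, x$cubic_scale, x$width_2theta, x$cell_scale)
  )
}

#' @rdname tidy.ice_mixture_fit
#' @method glance ice_mixture_fit
#' @export
glance.ice_mixture_fit <- function(x, ...) {
  tibble::tibble(
    cubic_fraction = x$cubic_fraction,
    residual = x$residual %||% NA_real_,
    converged = isTRUE(x$converged),
    flag = x$flag %||% NA_character_
  )
}

#' Tidy a GEV fit
#'
#' @param x A `gev_fit`.
#' @param ... Unused.
#' @return A tibble of parameter estimates.
#' @method tidy gev_fit
#' @export
tidy.gev_fit <- function(x, ...) {
  tibble::tibble(term = c("loc", "scale", "shape"),
                 estimate = c(x$loc, x$scale, x$shape))
}
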