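# ggplot2 diagnostics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a score profile
#'
#' The three score tracks versus inverse resolution with the ring
#' interpolation windows shaded — the standard per-data-set diagnostic.
#'
#' @param object An `ice_score_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ice_score_profile
#' @export
autoplot.ice_score_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s", "IFS", "DS", "OS")],
    cols = c("IFS", "DS", "OS"), names_to = "score", values_to = "value"
  )
  tab <- attr(object, "table")
  win <- tibble::tibble(lo = tab$interp_lo, hi = tab$interp_hi)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value)) +
    ggplot2::geom_rect(data = win,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                       ymin = -Inf, ymax = Inf, fill = "steelblue",
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~score, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(s ~ (ring(A)^-1)), y = NULL,
                  title = "Ice Finder, Depletion and Observation Scores") +
    ggplot2::theme_minimal()
}

#' Plot a powder pattern
#'
#' @param object A `powder_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot powder_pattern
#' @export
autoplot.powder_pattern <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$s, y = .data$intensity)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = expression(s ~ (ring(A)^-1)), y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit
#'
#' Observed pattern, fitted hexagonal+cubic model and background.
#'
#' @param object An `ice_mixture_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ice_mixture_fit
#' @export
autoplot.ice_mixture_fit <- function(object, ...) {
  if (is.null(object$fitted)) stop("nothing to plot: no ice signal",
                                   call. = FALSE)
  long <- tidyr::pivot_longer(object$fitted,
                              cols = c("observed", "model", "background"),
                              names_to = "track", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value,
                                     colour = .data$track)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = expression(s ~ (ring(A)^-1)), y = "intensity",
      title = sprintf("cubic fraction %.2f", object$cubic_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a detection report
#'
#' Per-ring ICS bars against the ring resolutions, annotated with the
#' classification and p-values.
#'
#' @param object An `ice_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ice_report
#' @export
autoplot.ice_report <- function(object, ...) {
  td <- tidy(object)
  if (!nrow(td)) stop("nothing to plot: set failed admission", call. = FALSE)
  td$ring <- sprintf("(%d%d%d)", td$h, td$k, td$l)
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$ring, -.data$d),
                                   y = .data$ics, fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "ice ring", y = "ICS",
      title = sprintf("%s  (p_ice = %.3g, p_obs = %.3g)",
                      object$classification, object$p_ice, object$p_obs)
    ) +
    ggplot2::theme_minimal()
}
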