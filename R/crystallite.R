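# Crystallite sizing from ring breadths: integral breadth measurement,
# instrumental (Voigt) deconvolution and the Scherrer equation.

#' Integral breadth of a peak
#'
#' Breadth = background-subtracted peak area / background-subtracted maximum
#' amplitude. The background is the straight line through the window edges
#' (mean of the outermost `n_edge` points on each side); the area is
#' trapezoidal.
#'
#' @param two_theta Abscissa (2-theta in degrees, or any consistent unit).
#' @param intensity Profile values.
#' @param window Length-2 range of `two_theta` containing a single peak;
#'   defaults to the full profile.
#' @param n_edge Points per side used for the background line.
#' @return The integral breadth in the abscissa's unit.
#' @export
integral_breadth <- function(two_theta, intensity, window = range(two_theta),
                             n_edge = 3) {
  w <- two_theta >= window[1] & two_theta <= window[2] & is.finite(intensity)
  x <- two_theta[w]; y <- intensity[w]
  if (length(x) < 2 * n_edge + 3) {
    stop("window too narrow for a breadth measurement", call. = FALSE)
  }
  ix <- seq_along(x)
  lo <- ix <= n_edge; hi <- ix > length(x) - n_edge
  x0 <- mean(x[lo]); y0 <- mean(y[lo])
  x1 <- mean(x[hi]); y1 <- mean(y[hi])
  bg <- y0 + (y1 - y0) * (x - x0) / (x1 - x0)
  yc <- y - bg
  h <- max(yc)
  if (h <= 0) stop("no peak above background in the window", call. = FALSE)
  area <- sum(diff(x) * (utils::head(yc, -1) + utils::tail(yc, -1)) / 2)
  area / h
}

# Integral breadth of a Voigt profile from its Gaussian and Lorentzian
# component breadths: beta_V = beta_G * exp(-k^2) / erfc(k) with
# k = beta_L / (sqrt(pi) beta_G). Evaluated on the log scale for stability.
voigt_breadth <- function(beta_g, beta_l) {
  if (beta_g <= 0) return(beta_l)
  if (beta_l <= 0) return(beta_g)
  k <- beta_l / (sqrt(pi) * beta_g)
  log_erfc <- log(2) + stats::pnorm(-k * sqrt(2), log.p = TRUE)
  beta_g * exp(-k^2 - log_erfc)
}

#' Remove instrumental broadening from a measured breadth
#'
#' The observed peak is the convolution of a Gaussian instrumental profile
#' (integral breadth `beta_source`, default 0.037 degrees) with the
#' intrinsic Lorentzian size broadening. The intrinsic Lorentzian breadth is
#' obtained by inverting the exact Voigt integral-breadth combination
#' beta_obs = beta_source exp(-k^2)/erfc(k), k = beta_L/(sqrt(pi)
#' beta_source), by bracketed root finding to 1e-10 relative.
#'
#' @param beta_obs Observed integral breadth (degrees 2-theta).
#' @param beta_source Instrumental (Gaussian) integral breadth, same unit.
#' @return The intrinsic Lorentzian integral breadth.
#' @export
deconvolve_instrumental <- function(beta_obs, beta_source = 0.037) {
  if (beta_source <= 0) return(beta_obs)
  if (beta_obs <= beta_source) {
    stop("observed breadth is below the instrumental resolution",
         call. = FALSE)
  }
  root <- stats::uniroot(
    function(bl) voigt_breadth(beta_source, bl) - beta_obs,
    lower = 1e-12, upper = beta_obs, tol = 1e-10 * beta_obs
  )
  root$root
}

#' Scherrer crystallite size
#'
#' delta = K lambda / (beta cos theta), with beta the integral breadth in
#' radians. The apparent size delta relates to the true size through
#' Scherrer's constant K, close to one. Size estimates are only meaningful
#' on the lowest-angle ring not broadened by stacking disorder — the (002)
#' ring of hexagonal ice — since strain and fault broadening grow faster
#' with angle; using another ring triggers a warning, not an error.
#'
#' @param beta Integral breadth in 2-theta degrees.
#' @param theta Bragg angle theta in degrees.
#' @param wavelength Wavelength in Angstrom.
#' @param K Scherrer constant (default 1).
#' @param ring Optional Miller triplet of the ring measured, checked against
#'   (0,0,2).
#' @return Apparent crystallite size in Angstrom.
#' @export
scherrer_size <- function(beta, theta, wavelength, K = 1, ring = NULL) {
  stopifnot(beta > 0, theta > 0, theta < 90)
  if (!is.null(ring) && !identical(as.integer(ring), c(0L, 0L, 2L))) {
    warning("crystallite size is calibrated for the (002) ring; other rings ",
            "carry strain and stacking-fault broadening", call. = FALSE)
  }
  beta_rad <- beta * pi / 180
  K * wavelength / (beta_rad * cos(theta * pi / 180))
}

#' Estimate ice-crystallite size from a 1D ring profile
#'
#' Full chain: integral breadth in the window, instrumental deconvolution,
#' Scherrer size. Returns the corrected size and the uncorrected size (the
#' full measured breadth fed to Scherrer's equation), a lower bound on the
#' true size.
#'
#' @param two_theta,intensity 1D profile in 2-theta degrees.
#' @param window 2-theta window around the ring.
#' @param wavelength Wavelength in Angstrom.
#' @param beta_source Instrumental Gaussian integral breadth in degrees.
#' @param K Scherrer constant.
#' @param ring Optional Miller triplet (see [scherrer_size()]).
#' @return A tibble with beta_raw, beta_corrected, size, size_uncorrected
#'   (both sizes in Angstrom).
#' @export
estimate_crystallite_size <- function(two_theta, intensity,
                                      window = range(two_theta),
                                      wavelength = 0.9795,
                                      beta_source = 0.037, K = 1,
                                      ring = NULL) {
  beta_raw <- integral_breadth(two_theta, intensity, window)
  w <- two_theta >= window[1] & two_theta <= window[2]
  centre <- two_theta[w][which.max(intensity[w])]
  theta <- centre / 2
  beta_corr <- deconvolve_instrumental(beta_raw, beta_source)
  tibble::tibble(
    two_theta = centre,
    beta_raw = beta_raw,
    beta_corrected = beta_corr,
    size = scherrer_size(beta_corr, theta, wavelength, K, ring),
    size_uncorrected = scherrer_size(beta_raw, theta, wavelength, K, ring)
  )
}
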