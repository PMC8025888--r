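# 2D frame analysis: detector geometry, azimuthal averaging, outlier (ice
# spot) detection and beam-geometry refinement.

#' Detector frame geometry
#'
#' Flat detector at `distance` mm along the beam, pixel pitch `pixel` mm,
#' beam centre in pixel coordinates, and two small tilt angles (degrees)
#' rotating the detector normal about the lab x and y axes.
#'
#' @param beam_x,beam_y Beam centre in pixels.
#' @param distance Sample-detector distance in mm.
#' @param pixel Pixel pitch in mm.
#' @param wavelength Wavelength in Angstrom.
#' @param tilt_x,tilt_y Detector tilts in degrees.
#' @return A `frame_geometry` list.
#' @export
frame_geometry <- function(beam_x, beam_y, distance, pixel, wavelength,
                           tilt_x = 0, tilt_y = 0) {
  stopifnot(distance > 0, pixel > 0, wavelength > 0)
  structure(list(beam_x = beam_x, beam_y = beam_y, distance = distance,
                 pixel = pixel, wavelength = wavelength,
                 tilt_x = tilt_x, tilt_y = tilt_y),
            class = "frame_geometry")
}

.rot_xy <- function(tx_deg, ty_deg) {
  tx <- tx_deg * pi / 180; ty <- ty_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(tx), sin(tx), 0, -sin(tx), cos(tx)), 3, 3)
  ry <- matrix(c(cos(ty), 0, -sin(ty), 0, 1, 0, sin(ty), 0, cos(ty)), 3, 3)
  rx %*% ry
}

# Inverse resolution s and azimuth phi for every pixel of an nx x ny frame.
# The detector plane passes through (0, 0, distance); its in-plane basis and
# normal are the rotated lab axes.
pixel_map <- function(geom, nx, ny) {
  R <- .rot_xy(geom$tilt_x, geom$tilt_y)
  ex <- R[, 1]; ey <- R[, 2]
  px <- (rep(seq_len(nx), ny) - geom$beam_x) * geom$pixel
  py <- (rep(seq_len(ny), each = nx) - geom$beam_y) * geom$pixel
  X <- px * ex[1] + py * ey[1]
  Y <- px * ex[2] + py * ey[2]
  Z <- geom$distance + px * ex[3] + py * ey[3]
  r <- sqrt(X^2 + Y^2 + Z^2)
  two_theta <- acos(pmin(pmax(Z / r, -1), 1))
  s <- 2 * sin(two_theta / 2) / geom$wavelength
  list(s = matrix(s, nx, ny), phi = matrix(atan2(Y, X), nx, ny))
}

# Exact inverse of pixel_map: pixel coordinates of the point at inverse
# resolution s and azimuth phi (ray-plane intersection).
s_phi_to_pixel <- function(geom, s, phi) {
  theta <- asin(pmin(s * geom$wavelength / 2, 1))
  tt <- 2 * theta
  v <- cbind(sin(tt) * cos(phi), sin(tt) * sin(phi), cos(tt))
  R <- .rot_xy(geom$tilt_x, geom$tilt_y)
  n <- R[, 3]; p0 <- c(0, 0, geom$distance)
  t <- sum(p0 * n) / (v %*% n)
  p <- v * as.vector(t)
  dxy <- sweep(p, 2, p0) %*% R[, 1:2]
  cbind(x = dxy[, 1] / geom$pixel + geom$beam_x,
        y = dxy[, 2] / geom$pixel + geom$beam_y)
}

#' Azimuthally average a frame
#'
#' Mean pixel value in uniform inverse-resolution bins; the 1D powder
#' pattern of the frame.
#'
#' @param frame Counts matrix, or a list with `counts` and `geometry`.
#' @param geometry A [frame_geometry()] (ignored if `frame` carries one).
#' @param n_bins Number of s bins.
#' @param mask Optional logical matrix; TRUE pixels are excluded.
#' @return A tibble with s (bin centre), intensity (mean counts), n_pix.
#' @export
azimuthal_average <- function(frame, geometry = NULL, n_bins = 500,
                              mask = NULL) {
  if (is.list(frame) && !is.null(frame$counts)) {
    geometry <- geometry %||% frame$geometry
    frame <- frame$counts
  }
  stopifnot(inherits(geometry, "frame_geometry"))
  maps <- pixel_map(geometry, nrow(frame), ncol(frame))
  use <- if (is.null(mask)) rep(TRUE, length(frame)) else !as.vector(mask)
  if (!any(use)) stop("fully masked frame", call. = FALSE)
  s <- as.vector(maps$s)[use]
  v <- as.vector(frame)[use]
  edges <- seq(min(s), max(s), length.out = n_bins + 1)
  idx <- .bin_index(s, edges)
  n <- tabulate(idx, n_bins)
  tot <- rep(0, n_bins)
  agg <- rowsum(v, idx)
  tot[as.integer(rownames(agg))] <- agg[, 1]
  tibble::tibble(s = (edges[-1] + edges[-n_bins - 1]) / 2,
                 intensity = ifelse(n > 0, tot / n, NA_real_),
                 n_pix = n)
}

#' Find isolated ice-diffraction spots (outlier pixels)
#'
#' A pixel is a spot when its value exceeds `threshold_multiple` (default 5)
#' times the local background, estimated as the median of its 21 x 21
#' neighbourhood. Candidates can be restricted to annuli around the expected
#' ice-ring positions and masked (protein-peak) pixels are excluded.
#'
#' @param frame Counts matrix or list with `counts` and `geometry`.
#' @param geometry A [frame_geometry()].
#' @param table Optional `ice_ring_table`; when given, the search is
#'   restricted to annuli of half-width `annulus_halfwidth` around its rings,
#'   and each spot is matched to the nearest ring.
#' @param threshold_multiple Detection threshold as a multiple of the local
#'   background.
#' @param protein_mask Optional logical matrix of pixels to exclude.
#' @param annulus_halfwidth Annulus half-width in 1/Angstrom.
#' @param d_match_tol Ring-match tolerance in Angstrom (default 0.01).
#' @return A tibble with x, y, value, background, s, d, ring_d, hex_match.
#' @export
find_ice_spots <- function(frame, geometry = NULL, table = NULL,
                           threshold_multiple = 5, protein_mask = NULL,
                           annulus_halfwidth = 0.02, d_match_tol = 0.01) {
  if (is.list(frame) && !is.null(frame$counts)) {
    geometry <- geometry %||% frame$geometry
    frame <- frame$counts
  }
  stopifnot(inherits(geometry, "frame_geometry"))
  m <- frame
  mx <- max(m, 1)
  bg <- EBImage::medianFilter(m / mx, size = 10) * mx
  cand <- m > threshold_multiple * pmax(bg, 1e-9)
  if (!is.null(protein_mask)) cand <- cand & !protein_mask
  maps <- pixel_map(geometry, nrow(m), ncol(m))
  if (!is.null(table)) {
    near <- matrix(FALSE, nrow(m), ncol(m))
    for (s0 in 1 / table$d) {
      near <- near | abs(maps$s - s0) <= annulus_halfwidth
    }
    cand <- cand & near
  }
  idx <- which(cand, arr.ind = TRUE)
  d_px <- 1 / maps$s[idx]
  out <- tibble::tibble(
    x = idx[, 1], y = idx[, 2],
    value = m[idx], background = bg[idx],
    s = maps$s[idx], d = d_px
  )
  if (!is.null(table)) {
    nearest <- vapply(out$d, function(d) table$d[which.min(abs(table$d - d))],
                      0)
    out$ring_d <- nearest
    out$hex_match <- abs(out$d - nearest) <= d_match_tol
  }
  out[order(-out$value), ]
}

#' Histogram of ice spots versus resolution
#'
#' @param spots Tibble from [find_ice_spots()] (needs a `d` column).
#' @param table An `ice_ring_table` giving the hexagonal ring positions.
#' @param d_tolerance Match tolerance in Angstrom.
#' @param oscillation_per_frame Oscillation range of the frame(s) in degrees;
#'   used for the spots-per-degree rate.
#' @param d_range Histogram range in Angstrom.
#' @param n_bins Number of histogram bins (uniform in d).
#' @return A list with `histogram` (tibble d_lo, d_hi, count), `fraction_at_rings`
#'   (NA when there are no spots), `spots_per_degree`, `n_spots`.
#' @export
spot_histogram <- function(spots, table, d_tolerance = 0.01,
                           oscillation_per_frame = 1, d_range = c(1.4, 10),
                           n_bins = 50) {
  edges <- seq(d_range[1], d_range[2], length.out = n_bins + 1)
  counts <- if (nrow(spots)) {
    tabulate(.bin_index(spots$d, edges), n_bins)
  } else {
    integer(n_bins)
  }
  at_ring <- if (nrow(spots)) {
    vapply(spots$d, function(d) any(abs(table$d - d) <= d_tolerance), TRUE)
  } else {
    logical()
  }
  list(
    histogram = tibble::tibble(d_lo = edges[-n_bins - 1], d_hi = edges[-1],
                               count = counts),
    fraction_at_rings = if (nrow(spots)) mean(at_ring) else NA_real_,
    spots_per_degree = sum(at_ring) / oscillation_per_frame,
    n_spots = nrow(spots)
  )
}

# Integral breadth (area/height) of the pattern peak nearest s0, with linear
# background from the window edges; NA when no usable peak. The height is a
# 3-bin running mean so one noisy, sparsely populated bin cannot fake a
# tall narrow peak.
.pattern_breadth_s <- function(pattern, s0, halfwidth = 0.01) {
  w <- pattern$s >= s0 - halfwidth & pattern$s <= s0 + halfwidth &
    is.finite(pattern$intensity)
  if (!is.null(pattern$n_pix)) w <- w & pattern$n_pix >= 5
  if (sum(w) < 5) return(NA_real_)
  x <- pattern$s[w]; y <- pattern$intensity[w]
  n_edge <- max(2, floor(sum(w) * 0.1))
  ix <- seq_along(x)
  edge <- c(utils::head(ix, n_edge), utils::tail(ix, n_edge))
  bgfit <- stats::lm.fit(cbind(1, x[edge]), y[edge])
  yc <- y - (bgfit$coefficients[1] + bgfit$coefficients[2] * x)
  h <- max(stats::filter(yc, rep(1 / 3, 3), sides = 2), na.rm = TRUE)
  if (!is.finite(h) || h <= 0) return(NA_real_)
  area <- sum(diff(x) * (utils::head(yc, -1) + utils::tail(yc, -1)) / 2)
  if (area <= 0) return(NA_real_)
  area / h
}

#' Refine beam geometry by minimizing ring breadths
#'
#' Derivative-free optimization of the beam centre and two detector tilts to
#' minimize the summed integral breadths of the visible ice rings in the
#' azimuthally averaged pattern — sharp rings mean a correct geometry.
#'
#' @param frame Counts matrix or list with `counts` and `geometry`.
#' @param table `ice_ring_table` with the rings to sharpen.
#' @param geometry Initial [frame_geometry()].
#' @param n_bins Azimuthal-average resolution.
#' @param halfwidth Breadth-measurement window half-width in 1/Angstrom;
#'   wide enough that a ring smeared by a few-pixel centre error stays
#'   inside its window.
#' @param refine_tilt Also refine the two detector tilts? The tilts are
#'   nearly degenerate with a beam-centre shift on a flat detector, so
#'   centre-only refinement is more stable when the tilts are known to be
#'   small.
#' @return A list with `geometry` (refined), `objective` (achieved breadth
#'   sum), `initial_objective`, `converged`.
#' @export
refine_geometry <- function(frame, table, geometry = NULL, n_bins = 600,
                            halfwidth = 0.02, refine_tilt = TRUE) {
  if (is.list(frame) && !is.null(frame$counts)) {
    geometry <- geometry %||% frame$geometry
    frame <- frame$counts
  }
  stopifnot(inherits(geometry, "frame_geometry"))
  s_max <- max(pixel_map(geometry, nrow(frame), ncol(frame))$s)
  rings_s <- (1 / table$d)[1 / table$d < 0.95 * s_max]
  if (length(rings_s) < 2) stop("need at least two visible rings",
                                call. = FALSE)
  objective <- function(par) {
    g <- frame_geometry(par[1], par[2], geometry$distance, geometry$pixel,
                        geometry$wavelength, par[3], par[4])
    pat <- azimuthal_average(frame, g, n_bins)
    b <- vapply(rings_s, function(s0) .pattern_breadth_s(pat, s0, halfwidth),
                0)
    if (all(is.na(b))) return(1e6)
    # a ring whose breadth cannot be measured is worse than any real ring:
    # charge it the full window width
    sum(b, na.rm = TRUE) + 2 * halfwidth * sum(is.na(b))
  }
  start <- c(geometry$beam_x, geometry$beam_y, geometry$tilt_x,
             geometry$tilt_y)
  f0 <- objective(start)
  # stage 1: beam centre alone (the dominant error), then optionally all four
  fit1 <- stats::optim(start[1:2],
                       function(p) objective(c(p, start[3:4])),
                       method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-8))
  fit <- if (refine_tilt) {
    stats::optim(c(fit1$par, start[3:4]), objective,
                 method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-8,
                                parscale = c(1, 1, 0.2, 0.2)))
  } else {
    list(par = c(fit1$par, start[3:4]), value = fit1$value,
         convergence = fit1$convergence)
  }
  if (fit$value <= f0) {
    list(geometry = frame_geometry(fit$par[1], fit$par[2],
                                   geometry$distance, geometry$pixel,
                                   geometry$wavelength, fit$par[3],
                                   fit$par[4]),
         objective = fit$value, initial_objective = f0,
         converged = fit$convergence == 0)
  } else {
    list(geometry = geometry, objective = f0, initial_objective = f0,
         converged = FALSE)
  }
}
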