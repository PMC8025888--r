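# Binned intensity statistics versus inverse resolution and the three score
# tracks: Ice Finder Score (inflated normalized mean), Depletion Score
# (deficit of below-mean intensities) and Observation Score (missing
# reflections). All tracks live on a fine grid of 0.0025 1/A bins; expected
# trends are built from coarse 0.01 1/A bins with the ice-ring regions
# excised and bridged by linear interpolation.

# Half-open binning [lo, hi); the top edge value falls in the last bin.
.bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(edges) - 1] <- NA_integer_
  idx
}

.bin_stats <- function(s, I, edges) {
  n_bins <- length(edges) - 1
  idx <- .bin_index(s, edges)
  N <- tabulate(idx, n_bins)
  sum_I <- rep(0, n_bins); sum_I2 <- rep(0, n_bins)
  ok <- !is.na(idx)
  agg <- rowsum(cbind(I[ok], I[ok]^2), idx[ok])
  at <- as.integer(rownames(agg))
  sum_I[at] <- agg[, 1]; sum_I2[at] <- agg[, 2]
  mean_I <- ifelse(N > 0, sum_I / N, NA_real_)
  var_I <- ifelse(N > 0, pmax(sum_I2 / N - mean_I^2, 0), NA_real_)
  tibble::tibble(
    s = (edges[-length(edges)] + edges[-1]) / 2,
    lo = edges[-length(edges)], hi = edges[-1],
    N = N, mean_I = mean_I, sd_I = sqrt(var_I)
  )
}

#' Coarse binned intensity statistics
#'
#' Bins reflections into half-open inverse-resolution bins of the given
#' width (default 0.01 1/A, starting at the data's smallest s) and reports
#' per-bin count, mean, population standard deviation and the fraction of
#' intensities strictly below the bin's own mean (ties count as not-below).
#'
#' @param refl A [reflection_set()].
#' @param width Bin width in 1/Angstrom.
#' @return A tibble with columns s (bin centre), lo, hi, N, mean_I, sd_I, D.
#' @export
coarse_stats <- function(refl, width = 0.01) {
  if (!nrow(refl)) stop("empty reflection set", call. = FALSE)
  edges <- .make_edges(range(refl$s), width)
  st <- .bin_stats(refl$s, refl$I, edges)
  idx <- .bin_index(refl$s, edges)
  below <- tabulate(idx[which(refl$I < st$mean_I[idx])], nrow(st))
  st$D <- ifelse(st$N > 0, below / st$N, NA_real_)
  st
}

.make_edges <- function(s_range, width) {
  n <- max(1, ceiling((s_range[2] - s_range[1]) / width - 1e-9))
  seq(s_range[1], by = width, length.out = n + 1)
}

# Gaussian smoothing on a uniform grid, kernel truncated at 4 sigma and
# renormalized near the edges (and across interior NAs).
gaussian_smooth <- function(y, grid_step, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma / grid_step))
  w <- stats::dnorm(seq(-half, half) * grid_step, sd = sigma)
  n <- length(y)
  ok <- is.finite(y)
  y0 <- ifelse(ok, y, 0)
  num <- rep(0, n); den <- rep(0, n)
  for (j in seq_along(w)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    valid <- src >= 1 & src <= n
    num[valid] <- num[valid] + w[j] * y0[src[valid]]
    den[valid] <- den[valid] + w[j] * ok[src[valid]]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

# Linear interpolation of (x, y) support points onto `xout`, bridging gaps;
# constant extension beyond the support, with an edge flag.
.interp_track <- function(x, y, xout) {
  keep <- is.finite(y)
  if (sum(keep) < 2) {
    stop("fewer than two off-window coarse bins: cannot build expectations",
         call. = FALSE)
  }
  edge <- min(xout) < min(x[keep]) - 1e-12 || max(xout) > max(x[keep]) + 1e-12
  list(y = stats::approx(x[keep], y[keep], xout, rule = 2)$y, edge = edge)
}

#' Score profile: IFS, DS and OS tracks on the fine grid
#'
#' Runs the whole per-data-set scoring pipeline: coarse statistics, excision
#' of the ring interpolation windows, linear interpolation of the expected
#' trends, resampling to the fine grid, Gaussian smoothing of the expected
#' normalized mean f and expected count N-bar (sd 0.01 1/A), and the three
#' score tracks:
#' \itemize{
#'   \item IFS = sqrt(N) (mean/sd - f): positive when the bin's normalized
#'     mean intensity is inflated relative to the off-ring trend f.
#'     Undefined for N < 3.
#'   \item DS = (D-bar - D)/sigma_off: positive when the fraction of
#'     intensities below the expected mean is depleted; sigma_off is the
#'     standard deviation of (D-bar - D) over off-window bins.
#'   \item OS = (N-bar - N)/sqrt(N-bar): positive when reflections are
#'     missing relative to the smooth count trend.
#' }
#' The below-mean indicator for D compares each intensity against the
#' interpolated expected mean at its fine bin (strict inequality).
#'
#' @param refl A [reflection_set()].
#' @param table An `ice_ring_table` with windows ([assign_windows()]).
#' @param fine_width,coarse_width Bin widths in 1/Angstrom.
#' @param smooth_sigma Gaussian smoothing sd in 1/Angstrom for f and N-bar.
#' @return An `ice_score_profile` tibble: s, N, mean_I, sd_I, D, mu (expected
#'   mean), f, D_bar, N_bar, IFS, DS, OS, off_window; attributes carry the
#'   ring table and QC flags.
#' @export
score_profile <- function(refl, table, fine_width = 0.0025,
                          coarse_width = 0.01, smooth_sigma = 0.01) {
  stopifnot(inherits(refl, "reflection_set"),
            inherits(table, "ice_ring_table"))
  if (is.null(table$interp_lo)) table <- assign_windows(table)
  flags <- attr(refl, "flags") %||% character()

  s_range <- range(refl$s)
  regions <- interp_regions(table)
  # Clip regions to the data range; drop rings wholly outside it.
  regions <- regions[regions[, 1] <= s_range[2] &
                     regions[, 2] >= s_range[1], , drop = FALSE]

  co <- coarse_stats(refl, coarse_width)
  co_off <- if (nrow(regions)) !in_regions(co$s, regions) else
    rep(TRUE, nrow(co))

  fine_edges <- .make_edges(s_range, fine_width)
  fi <- .bin_stats(refl$s, refl$I, fine_edges)

  usable <- co_off & co$N >= 3 & is.finite(co$sd_I) & co$sd_I > 0
  mu_t <- .interp_track(co$s[usable], co$mean_I[usable], fi$s)
  sd_t <- .interp_track(co$s[usable], co$sd_I[usable], fi$s)
  f_raw <- mu_t$y / sd_t$y
  f <- gaussian_smooth(f_raw, fine_width, smooth_sigma)

  d_usable <- co_off & co$N >= 1 & is.finite(co$D)
  D_bar <- .interp_track(co$s[d_usable], co$D[d_usable], fi$s)$y

  # Per-fine-bin below-expected-mean fraction.
  idx <- .bin_index(refl$s, fine_edges)
  below <- tabulate(idx[which(refl$I < mu_t$y[idx])], nrow(fi))
  D <- ifelse(fi$N > 0, below / fi$N, NA_real_)

  # Expected count: excise ring regions from the fine counts, bridge, smooth.
  fine_in <- if (nrow(regions)) in_regions(fi$s, regions) else
    rep(FALSE, nrow(fi))
  N_src <- ifelse(fine_in, NA_real_, as.numeric(fi$N))
  N_bar <- .interp_track(fi$s, N_src, fi$s)$y
  N_bar <- gaussian_smooth(N_bar, fine_width, smooth_sigma)

  if (mu_t$edge || sd_t$edge) flags <- union(flags, "edge-window")

  # The bin's normalized mean uses the interpolated trend sd as sigma: the
  # fine bin's own sd is a noisy, downward-biased estimate at N ~ 100 and
  # would both bias the null IFS upward and dampen genuine ring bias
  # (which inflates the local sd along with the mean).
  IFS <- ifelse(fi$N >= 3 & is.finite(sd_t$y) & sd_t$y > 0,
                sqrt(fi$N) * (fi$mean_I / sd_t$y - f), NA_real_)
  diffD <- D_bar - D
  off_window <- !fine_in
  n_off <- sum(off_window & is.finite(diffD))
  if (n_off < 20) {
    stop("fewer than 20 off-window fine bins: cannot normalize DS",
         call. = FALSE)
  }
  sigma_off <- stats::sd(diffD[off_window], na.rm = TRUE)
  if (!is.finite(sigma_off) || sigma_off == 0) {
    stop("degenerate intensity distribution: off-window DS spread is zero",
         call. = FALSE)
  }
  DS <- diffD / sigma_off
  OS <- (N_bar - fi$N) / sqrt(pmax(N_bar, 1e-9))
  OS[N_bar <= 0] <- 0

  out <- tibble::tibble(
    s = fi$s, N = fi$N, mean_I = fi$mean_I, sd_I = fi$sd_I, D = D,
    mu = mu_t$y, sigma = sd_t$y, f = f, D_bar = D_bar, N_bar = N_bar,
    IFS = IFS, DS = DS, OS = OS, off_window = off_window
  )
  structure(out, class = c("ice_score_profile", class(out)),
            table = table, flags = flags, fine_width = fine_width,
            n_reflections = nrow(refl), d_range = rev(1 / s_range),
            source_label = attr(refl, "source_label"))
}

#' @export
print.ice_score_profile <- function(x, ...) {
  cat(sprintf("<ice_score_profile> %d fine bins (%d off-window), %d reflections\n",
              nrow(x), sum(x$off_window), attr(x, "n_reflections")))
  NextMethod()
}

#' Export a score profile as a tidy tab-separated table
#'
#' @param profile An `ice_score_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolated expectation tracks
#'
#' Convenience accessor for the expected trends the scores compare against:
#' runs the pipeline of [score_profile()] and returns only the fine-grid
#' expectation columns (mu, sigma, f, D_bar, N_bar).
#'
#' @inheritParams score_profile
#' @return A tibble with s, mu, sigma, f, D_bar, N_bar.
#' @export
interpolate_expectations <- function(refl, table, fine_width = 0.0025,
                                     coarse_width = 0.01,
                                     smooth_sigma = 0.01) {
  prof <- score_profile(refl, table, fine_width, coarse_width, smooth_sigma)
  tibble::as_tibble(prof)[, c("s", "mu", "sigma", "f", "D_bar", "N_bar")]
}
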