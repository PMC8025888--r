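# Synthetic data with known ground truth: Wilson-distributed reflection
# sets, ring-localized intensity bias, reflection exclusions, and 2D frames.
# Every generator is deterministic given its seed.

#' Triclinic cell sized for a target reflection count
#'
#' Builds a mildly triclinic "protein" cell whose reciprocal lattice holds at
#' least `n_target` reflections between `d_min` and `d_max`, so that a
#' synthetic reflection set can be subsampled from real lattice geometry.
#' The low symmetry avoids accidental d-spacing degeneracies, giving an
#' almost continuous distribution of inverse resolutions with the natural
#' s-squared density of reciprocal space.
#'
#' @param n_target Reflections wanted.
#' @param d_min,d_max Resolution range in Angstrom.
#' @param margin Enumerate this factor more than `n_target`.
#' @return A [unit_cell()].
#' @export
synthetic_cell <- function(n_target, d_min, d_max = Inf, margin = 1.3) {
  base <- unit_cell(7.91, 10.13, 11.57, 83.2, 97.4, 88.3)
  v_needed <- margin * n_target * 2 /
    ((4 * pi / 3) * (1 / d_min^3 - if (is.finite(d_max)) 1 / d_max^3 else 0))
  t <- (v_needed / base$volume)^(1 / 3)
  unit_cell(7.91 * t, 10.13 * t, 11.57 * t, 83.2, 97.4, 88.3)
}

#' Enumerate the unique-reflection pool of a cell
#'
#' All symmetry-unique (one hemisphere, Friedel mates folded) Miller triplets
#' with d in `[d_min, d_max]`. Enumerating the pool once and subsampling is
#' how repeated simulations amortize the lattice enumeration.
#'
#' @param cell A [unit_cell()].
#' @param d_min,d_max Resolution range in Angstrom.
#' @return Tibble with h, k, l, d, s.
#' @export
reflection_pool <- function(cell, d_min, d_max = Inf) {
  stopifnot(d_min > 0)
  nmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min)
  grid <- as.matrix(expand.grid(h = 0:nmax[1], k = -nmax[2]:nmax[2],
                                l = -nmax[3]:nmax[3]))
  keep <- grid[, 1] > 0 | (grid[, 1] == 0 & grid[, 2] > 0) |
    (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] > 0)
  grid <- grid[keep, , drop = FALSE]
  d <- d_spacing(cell, grid)
  sel <- d >= d_min & d <= d_max
  ds <- d[sel]
  tibble::tibble(h = grid[sel, 1], k = grid[sel, 2], l = grid[sel, 3],
                 d = ds, s = 1 / ds)
}

#' Simulate a Wilson-statistics reflection set
#'
#' Draws acentric intensities I ~ Exponential with mean
#' Sigma(s) = wilson_scale * exp(-B_protein s^2 / 2), the Wilson fall-off of
#' protein diffraction, on Miller indices subsampled from a triclinic
#' lattice. Reported uncertainties follow a fractional-plus-additive model
#' and zero-mean Gaussian measurement noise of that width is added, so weak
#' intensities can be negative, as in background-subtracted data.
#'
#' @param n_reflections Number of records.
#' @param d_min,d_max Resolution range in Angstrom.
#' @param wilson_scale Intensity scale (arbitrary units).
#' @param b_protein Wilson B factor in Angstrom^2 (default 35, a typical
#'   protein value).
#' @param sigma_frac,sigma_add Fractional and additive (in units of the local
#'   Wilson mean) components of the uncertainty model.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param cell Optional [unit_cell()]; sized automatically when omitted.
#' @param pool Optional precomputed [reflection_pool()] (must match `cell`).
#' @return A [reflection_set()] with attributes `wilson_scale` and
#'   `b_protein` used later by [inject_ice_bias()].
#' @export
simulate_reflections <- function(n_reflections = 20000, d_min = 1.8,
                                 d_max = 30, wilson_scale = 1000,
                                 b_protein = 35, sigma_frac = 0.05,
                                 sigma_add = 0.03, seed = 1, cell = NULL,
                                 pool = NULL) {
  if (!(d_min > 0 && d_min < d_max)) {
    stop("empty resolution range", call. = FALSE)
  }
  if (is.null(cell)) cell <- synthetic_cell(n_reflections, d_min, d_max)
  if (is.null(pool)) pool <- reflection_pool(cell, d_min, d_max)
  if (nrow(pool) < n_reflections) {
    stop("reflection pool smaller than n_reflections; enlarge the cell",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    take <- sample.int(nrow(pool), n_reflections)
    sub <- pool[take, ]
    Sigma <- wilson_scale * exp(-b_protein * sub$s^2 / 2)
    I_true <- stats::rexp(n_reflections, rate = 1 / Sigma)
    sigI <- sigma_frac * I_true + sigma_add * Sigma
    I_obs <- I_true + stats::rnorm(n_reflections, 0, sigI)
    refl <- reflection_set(
      tibble::tibble(h = sub$h, k = sub$k, l = sub$l, I = I_obs, sigI = sigI),
      cell, source_label = sprintf("synthetic seed=%d", seed)
    )
  })
  attr(refl, "wilson_scale") <- wilson_scale
  attr(refl, "b_protein") <- b_protein
  refl
}

# Local Wilson mean for a reflection set: stored parameters when the set is
# synthetic, otherwise a coarse-bin estimate interpolated to each s.
.local_mean <- function(refl) {
  ws <- attr(refl, "wilson_scale"); bp <- attr(refl, "b_protein")
  if (!is.null(ws) && !is.null(bp)) return(ws * exp(-bp * refl$s^2 / 2))
  co <- coarse_stats(refl)
  ok <- co$N >= 3
  stats::approx(co$s[ok], co$mean_I[ok], refl$s, rule = 2)$y
}

#' Inject ring-localized intensity bias
#'
#' Adds the background-subtraction artifact of an ice ring to the intensities
#' inside each ring's interpolation window: a positive Lorentzian core at the
#' ring position (background underestimated under a direct overlap) with
#' negative flanks (background overestimated next to the ring),
#' \deqn{b(s) = A \Sigma(s) [L(s - s_0) - \phi (1 - L(s - s_0))],}
#' where L is a unit-peak Lorentzian of half-width `width`, A the amplitude
#' in units of the local Wilson mean \eqn{\Sigma(s)}, and \eqn{\phi} the
#' flank depth fraction. Records outside the interpolation windows are
#' untouched. The bias is multiplicative in the local mean, so score
#' invariance under a global intensity rescale is preserved.
#'
#' @param refl A [reflection_set()].
#' @param table An `ice_ring_table` with windows.
#' @param amplitude Bias amplitude A (may be a vector, one per ring used).
#' @param width Lorentzian half-width at half maximum in 1/Angstrom.
#' @param flank_fraction Depth of the negative flanks as a fraction of A.
#' @param rings Which rings of `table` to use: "all" (default; the table
#'   passed in is already the selection), "common" or "hexagonal_only".
#' @return The biased reflection set.
#' @export
inject_ice_bias <- function(refl, table, amplitude, width = 0.001,
                            flank_fraction = 0.2, rings = "all") {
  stopifnot(inherits(refl, "reflection_set"))
  if (is.null(table$interp_lo)) table <- assign_windows(table)
  sub <- if (identical(rings, "all")) table else
    table[table$category %in% rings, , drop = FALSE]
  if (!nrow(sub)) return(refl)
  amplitude <- rep_len(amplitude, nrow(sub))
  Sigma <- .local_mean(refl)
  for (i in seq_len(nrow(sub))) {
    inside <- refl$s >= sub$interp_lo[i] & refl$s <= sub$interp_hi[i]
    if (!any(inside)) next
    L <- 1 / (1 + ((refl$s[inside] - 1 / sub$d[i]) / width)^2)
    refl$I[inside] <- refl$I[inside] +
      amplitude[i] * Sigma[inside] * (L - flank_fraction * (1 - L))
  }
  refl
}

#' Remove reflections inside ring windows
#'
#' Deletes a given fraction of the records inside each selected ring's
#' window, uniformly at random, emulating an experimenter excluding
#' resolution shells around the ice rings.
#'
#' @inheritParams inject_ice_bias
#' @param fraction Removal fraction in [0, 1].
#' @param window "search" or "interp": which window to excise.
#' @param seed Integer seed.
#' @return The thinned reflection set.
#' @export
inject_exclusions <- function(refl, table, fraction, window = "search",
                              seed = 1, rings = "all") {
  stopifnot(fraction >= 0, fraction <= 1)
  if (is.null(table$interp_lo)) table <- assign_windows(table)
  sub <- if (identical(rings, "all")) table else
    table[table$category %in% rings, , drop = FALSE]
  if (!nrow(sub) || fraction == 0) return(refl)
  lo <- if (window == "search") sub$search_lo else sub$interp_lo
  hi <- if (window == "search") sub$search_hi else sub$interp_hi
  drop_idx <- integer()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(sub))) {
      inside <- which(refl$s >= lo[i] & refl$s <= hi[i])
      n_drop <- round(fraction * length(inside))
      if (n_drop > 0) {
        drop_idx <- c(drop_idx, sample(inside, n_drop))
      }
    }
  })
  if (length(drop_idx)) refl <- refl[-unique(drop_idx), ]
  refl
}

#' Specify a synthetic diffraction frame
#'
#' @param nx,ny Detector size in pixels.
#' @param pixel Pixel pitch in mm.
#' @param distance Sample-detector distance in mm.
#' @param wavelength Wavelength in Angstrom.
#' @param centre Beam centre in pixels (length 2); defaults to the middle.
#' @param background Mean Poisson background in counts.
#' @param rings Tibble/data frame with columns d (Angstrom), amplitude
#'   (peak counts), width (radial Lorentzian HWHM in 1/Angstrom), lumpiness
#'   (von Mises concentration; 0 = isotropic ring).
#' @param spots Tibble/data frame with columns d, count (number of spots on
#'   the ring) and multiple (pixel value as a multiple of the background).
#' @param seed Integer seed.
#' @return A `frame_spec` list.
#' @export
frame_spec <- function(nx = 512, ny = 512, pixel = 0.172, distance = 150,
                       wavelength = 0.9795, centre = NULL, background = 50,
                       rings = NULL, spots = NULL, seed = 1) {
  structure(list(nx = nx, ny = ny, pixel = pixel, distance = distance,
                 wavelength = wavelength,
                 centre = centre %||% c(nx / 2 + 0.5, ny / 2 + 0.5),
                 background = background, rings = rings, spots = spots,
                 seed = seed),
            class = "frame_spec")
}

#' Simulate a 2D diffraction frame
#'
#' Poisson background, powder rings as radial Lorentzians (optionally
#' modulated azimuthally by a three-component von Mises mixture to emulate
#' lumpy rings from few large grains) and isolated single-pixel hot spots at
#' stated multiples of the background, placed at ring radii.
#'
#' @param spec A [frame_spec()].
#' @return A list with `counts` (nx x ny integer matrix), `geometry`
#'   ([frame_geometry()]), `truth` (spot pixel coordinates and skipped
#'   rings).
#' @export
simulate_frame <- function(spec) {
  stopifnot(inherits(spec, "frame_spec"))
  geom <- frame_geometry(beam_x = spec$centre[1], beam_y = spec$centre[2],
                         distance = spec$distance, pixel = spec$pixel,
                         wavelength = spec$wavelength)
  maps <- pixel_map(geom, spec$nx, spec$ny)
  s_max <- max(maps$s)
  mu <- matrix(spec$background, spec$nx, spec$ny)
  skipped <- character()
  withr::with_seed(spec$seed, {
    if (!is.null(spec$rings)) {
      for (i in seq_len(nrow(spec$rings))) {
        r <- spec$rings[i, ]
        s0 <- 1 / r$d
        if (s0 > s_max) {
          skipped <- c(skipped, sprintf("ring d=%.3f outside detector", r$d))
          next
        }
        radial <- r$amplitude / (1 + ((maps$s - s0) / r$width)^2)
        if (r$lumpiness > 0) {
          centres <- stats::runif(3, -pi, pi)
          modu <- rowMeans(vapply(centres, function(c0)
            exp(r$lumpiness * cos(as.vector(maps$phi) - c0)),
            numeric(length(maps$phi))))
          modu <- modu / mean(modu)
          radial <- radial * matrix(modu, spec$nx, spec$ny)
        }
        mu <- mu + radial
      }
    }
    counts <- matrix(stats::rpois(length(mu), as.vector(mu)),
                     spec$nx, spec$ny)
    spot_xy <- NULL
    if (!is.null(spec$spots)) {
      for (i in seq_len(nrow(spec$spots))) {
        sp <- spec$spots[i, ]
        s0 <- 1 / sp$d
        if (s0 > s_max) {
          skipped <- c(skipped, sprintf("spot ring d=%.3f outside detector",
                                        sp$d))
          next
        }
        phi <- stats::runif(sp$count, -pi, pi)
        px <- s_phi_to_pixel(geom, rep(s0, sp$count), phi)
        px <- round(px)
        ok <- px[, 1] >= 1 & px[, 1] <= spec$nx &
          px[, 2] >= 1 & px[, 2] <= spec$ny
        px <- px[ok, , drop = FALSE]
        counts[px] <- round(sp$multiple * spec$background)
        spot_xy <- rbind(spot_xy, cbind(px, d = rep(sp$d, nrow(px))))
      }
    }
  })
  list(counts = counts, geometry = geom,
       truth = list(spots = spot_xy, skipped = skipped))
}

#' Write / read a frame as plain text
#'
#' Portable flat-text container for synthetic frames: a header comment with
#' the geometry followed by the counts matrix.
#'
#' @param frame List with `counts` and `geometry` as from [simulate_frame()].
#' @param path File path.
#' @return `path` (write) or a frame list (read).
#' @export
write_frame_text <- function(frame, path) {
  g <- frame$geometry
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# geometry %g %g %g %g %g %g %g",
                     g$beam_x, g$beam_y, g$distance, g$pixel, g$wavelength,
                     g$tilt_x, g$tilt_y), con)
  utils::write.table(frame$counts, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_text
#' @export
read_frame_text <- function(path) {
  hdr <- readLines(path, n = 1)
  v <- as.numeric(strsplit(sub("^#\\s*geometry\\s*", "", hdr), "\\s+")[[1]])
  counts <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(counts) <- NULL
  list(counts = counts,
       geometry = frame_geometry(v[1], v[2], v[3], v[4], v[5], v[6], v[7]))
}
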