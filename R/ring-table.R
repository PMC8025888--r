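# Powder ring tables for the ice polymorphs, generated from lattice
# parameters and oxygen-only structure factors (hydrogen contributes ~1/8 of
# the scattering and does not change any extinction).

# Cromer-Mann 4-Gaussian coefficients for neutral O (International Tables C).
.o_scatter <- list(
  a = c(3.0485, 2.2868, 1.5463, 0.8670),
  b = c(13.2771, 5.7011, 0.3239, 32.9089),
  c = 0.2508
)

# Atomic scattering factor of oxygen at inverse resolution s (1/A).
o_form_factor <- function(s) {
  q2 <- (s / 2)^2  # (sin theta / lambda)^2
  vapply(q2, function(x) sum(.o_scatter$a * exp(-.o_scatter$b * x)), 0) +
    .o_scatter$c
}

# Oxygen fractional coordinates of the two reference arrangements.
.hex_oxygens <- function(z = 1 / 16) {
  rbind(
    c(1 / 3, 2 / 3, z),
    c(2 / 3, 1 / 3, -z),
    c(2 / 3, 1 / 3, 1 / 2 + z),
    c(1 / 3, 2 / 3, 1 / 2 - z)
  )
}

.cubic_oxygens <- function() {
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+"))
}

# Enumerate all reflections of `cell` with d in [d_min, d_max], compute
# oxygen-only |F|^2 (no Debye-Waller factor), and merge coincident positions
# into powder rings with summed multiplicity.
ring_enumerate <- function(cell, frac_coords, d_min, d_max,
                           extinction_rel = 1e-6) {
  if (!(d_min > 0 && d_min < d_max)) {
    stop("need 0 < d_min < d_max", call. = FALSE)
  }
  nmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min)
  grid <- as.matrix(expand.grid(h = -nmax[1]:nmax[1],
                                k = -nmax[2]:nmax[2],
                                l = -nmax[3]:nmax[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- d_spacing(cell, grid)
  keep <- d >= d_min & d <= d_max
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  if (!length(d)) stop("no reflections in the requested d range", call. = FALSE)

  s <- 1 / d
  phase <- 2 * pi * (grid %*% t(frac_coords))
  f0 <- o_form_factor(s)
  f_re <- rowSums(cos(phase)) * f0
  f_im <- rowSums(sin(phase)) * f0
  f2 <- f_re^2 + f_im^2

  # Merge rings: group reflections whose d agree to a relative 1e-6.
  ord <- order(-d)
  d <- d[ord]; f2 <- f2[ord]; grid <- grid[ord, , drop = FALSE]
  new_ring <- c(TRUE, abs(diff(d)) > 1e-6 * d[-1])
  ring_id <- cumsum(new_ring)
  rep_idx <- which(new_ring)
  # representative hkl: the lexicographically largest non-negative-leaning one
  rep_hkl <- t(vapply(split(seq_along(ring_id), ring_id), function(ix) {
    sub <- grid[ix, , drop = FALSE]
    score <- (sub[, 1] >= 0) * 4 + (sub[, 2] >= 0) * 2 + (sub[, 3] >= 0)
    sub <- sub[order(-score, -sub[, 1], -sub[, 2], -sub[, 3]), , drop = FALSE]
    sub[1, ]
  }, c(h = 0L, k = 0L, l = 0L)))
  dimnames(rep_hkl) <- NULL

  out <- tibble::tibble(
    h = rep_hkl[, 1], k = rep_hkl[, 2], l = rep_hkl[, 3],
    d = d[rep_idx],
    m = as.integer(tabulate(ring_id)),
    F2 = as.numeric(vapply(split(f2, ring_id), mean, 0))
  )
  out[out$F2 > extinction_rel * max(out$F2), , drop = FALSE]
}

.as_ring_table <- function(rings, hex_cell, cubic_cell) {
  structure(rings, class = c("ice_ring_table", class(rings)),
            hex_cell = hex_cell, cubic_cell = cubic_cell)
}

#' Hexagonal-ice powder ring table
#'
#' Enumerates every powder ring of hexagonal ice (Ih) with resolution in
#' `[d_min, d_max]`, computed from the wurtzite-type oxygen arrangement
#' (four O per cell at +/-(1/3, 2/3, z) and +/-(2/3, 1/3, 1/2+z), z = 0.0629).
#' Structure factors are oxygen-only; rings whose |F|^2 falls below
#' `extinction_rel` times the strongest ring are systematic absences and are
#' dropped. Symmetry-coincident reflections are merged into single rings with
#' summed multiplicity. Each ring is categorized `common` when a cubic-ice
#' ring (diamond-type lattice, same d range) lies within `match_tol` of it,
#' else `hexagonal_only`; with the default cells exactly the (002), (110) and
#' (112) rings are common, and 11 rings lie between 4 and 1.5 Angstrom.
#'
#' @param cell Hexagonal cell; default from [ice_cells()].
#' @param d_min,d_max Resolution range in Angstrom.
#' @param cubic_cell Cubic reference cell used for the common-ring match.
#' @param match_tol Matching tolerance in Angstrom (default 0.02).
#' @param extinction_rel Relative |F|^2 threshold below which a ring is
#'   treated as extinct.
#' @return An `ice_ring_table`: a tibble with columns h, k, l, d, m
#'   (multiplicity), F2 (oxygen-only squared structure factor) and category,
#'   sorted by descending d. Pass it to [assign_windows()] before scoring.
#' @examples
#' hexagonal_ring_table(d_min = 1.5, d_max = 4)
#' @export
hexagonal_ring_table <- function(cell = ice_cells()$hex, d_min = 1.5,
                                 d_max = 4, cubic_cell = ice_cells()$cubic,
                                 match_tol = 0.02, extinction_rel = 1e-6) {
  rings <- ring_enumerate(cell, .hex_oxygens(), d_min, d_max, extinction_rel)
  cub <- ring_enumerate(cubic_cell, .cubic_oxygens(), d_min, d_max,
                        extinction_rel)
  is_common <- vapply(rings$d, function(d) any(abs(cub$d - d) <= match_tol),
                      TRUE)
  rings$category <- ifelse(is_common, "common", "hexagonal_only")
  .as_ring_table(rings, hex_cell = cell, cubic_cell = cubic_cell)
}

#' Cubic-ice powder ring table
#'
#' Enumerates the powder rings of cubic ice (Ic) from the diamond-type oxygen
#' arrangement (eight O per cell: face-centred positions plus the
#' (1/4,1/4,1/4) basis). Diamond-structure extinctions (mixed indices;
#' h+k+l = 4n+2 with all-even indices) emerge from the structure-factor
#' threshold rather than being hard-coded. Rings coincident with a
#' hexagonal common ring are categorized `common`, the rest `other`.
#'
#' @inheritParams hexagonal_ring_table
#' @param hex_cell Hexagonal reference cell used for the match.
#' @return An `ice_ring_table` tibble (see [hexagonal_ring_table()]).
#' @export
cubic_ring_table <- function(cell = ice_cells()$cubic, d_min = 1.5, d_max = 4,
                             hex_cell = ice_cells()$hex, match_tol = 0.02,
                             extinction_rel = 1e-6) {
  rings <- ring_enumerate(cell, .cubic_oxygens(), d_min, d_max, extinction_rel)
  hex <- hexagonal_ring_table(hex_cell, d_min, d_max, cubic_cell = cell,
                              match_tol = match_tol,
                              extinction_rel = extinction_rel)
  hex_common_d <- hex$d[hex$category == "common"]
  is_common <- vapply(rings$d, function(d)
    length(hex_common_d) && any(abs(hex_common_d - d) <= match_tol), TRUE)
  rings$category <- ifelse(is_common, "common", "other")
  .as_ring_table(rings, hex_cell = hex_cell, cubic_cell = cell)
}

#' Attach search and interpolation windows to a ring table
#'
#' Each ring receives two intervals in inverse resolution, centred at
#' s = 1/d: a narrow search window in which score maxima are taken, and a
#' wider interpolation window excised from the background-trend estimate.
#' Defaults (+/-0.003 and +/-0.010 1/A) sit inside the ~0.005 1/A width of
#' the intensity regions biased by ice. Overlapping interpolation windows of
#' neighbouring rings simply merge at excision time; overlapping *search*
#' windows of two common rings would make per-ring maxima ambiguous and are
#' an error.
#'
#' @param table An `ice_ring_table`.
#' @param search_halfwidth,interp_halfwidth Window half-widths in 1/Angstrom;
#'   `search_halfwidth <= interp_halfwidth` is required.
#' @return The table with columns search_lo, search_hi, interp_lo, interp_hi
#'   added (units 1/Angstrom).
#' @export
assign_windows <- function(table, search_halfwidth = 0.003,
                           interp_halfwidth = 0.010) {
  stopifnot(inherits(table, "ice_ring_table"))
  if (!(search_halfwidth > 0 && search_halfwidth <= interp_halfwidth)) {
    stop("need 0 < search_halfwidth <= interp_halfwidth", call. = FALSE)
  }
  s0 <- 1 / table$d
  table$search_lo <- s0 - search_halfwidth
  table$search_hi <- s0 + search_halfwidth
  table$interp_lo <- s0 - interp_halfwidth
  table$interp_hi <- s0 + interp_halfwidth
  com <- table[table$category == "common", , drop = FALSE]
  if (nrow(com) > 1) {
    ord <- order(com$search_lo)
    if (any(com$search_lo[ord][-1] < com$search_hi[ord][-nrow(com)])) {
      stop("search windows of common rings overlap; reduce search_halfwidth",
           call. = FALSE)
    }
  }
  table
}

# Union of interpolation windows as a two-column matrix of disjoint regions.
interp_regions <- function(table) {
  stopifnot(!is.null(table$interp_lo))
  lo <- sort(table$interp_lo)
  hi <- table$interp_hi[order(table$interp_lo)]
  out_lo <- lo[1]; out_hi <- hi[1]; res <- NULL
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi) {
      out_hi <- max(out_hi, hi[i])
    } else {
      res <- rbind(res, c(out_lo, out_hi))
      out_lo <- lo[i]; out_hi <- hi[i]
    }
  }
  rbind(res, c(out_lo, out_hi))
}

in_regions <- function(x, regions) {
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (x >= regions[i, 1] & x <= regions[i, 2])
  }
  hit
}

#' Export a ring table as tab-separated text
#'
#' @param table An `ice_ring_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ring_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
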