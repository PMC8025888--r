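# Ring-table generation, windows, powder synthesis and mixture fitting.

ref_positions <- c(3.895, 3.661, 3.438, 2.667, 2.249, 2.068, 1.947, 1.916,
                   1.882, 1.719, 1.522)  # hexagonal-ice rings, 4-1.5 A

test_that("hexagonal table has 11 rings at the reference positions, 3 common", {
  tab <- hexagonal_ring_table(d_min = 1.5, d_max = 4)
  expect_equal(nrow(tab), 11)
  expect_equal(sum(tab$category == "common"), 3)
  expect_equal(tab$d, ref_positions, tolerance = 1e-3)
  common <- tab[tab$category == "common", ]
  expect_equal(common[, c("h", "k", "l")],
               tibble::tibble(h = c(0, 1, 1), k = c(0, 1, 1), l = c(2, 0, 2)),
               ignore_attr = TRUE)
  # rounded positions match at the printed precision
  expect_equal(round(common$d, 3), c(3.661, 2.249, 1.916))
  expect_equal(round(tab$d[tab$h == 2 & tab$k == 0 & tab$l == 2], 2), 1.72)
  expect_equal(round(tab$d[tab$h == 2 & tab$k == 0 & tab$l == 3], 2), 1.52)
})

test_that("wurtzite extinctions remove (111) and the near-axial l-odd rings", {
  tab <- hexagonal_ring_table(d_min = 1.5, d_max = 4)
  expect_false(any(tab$h == 1 & tab$k == 1 & tab$l == 1))
  d111 <- d_spacing(ice_cells()$hex, c(1, 1, 1))
  expect_false(any(abs(tab$d - d111) < 1e-3))
})

test_that("cubic table shows diamond extinctions and matches the common rings", {
  tab <- cubic_ring_table(d_min = 1.5, d_max = 4)
  # (200) is diamond-forbidden
  expect_false(any(tab$h == 2 & tab$k == 0 & tab$l == 0))
  # (111) present at the brute-force position
  d111 <- d_spacing_oracle(6.358, 6.358, 6.358, 90, 90, 90, c(1, 1, 1))
  expect_true(any(abs(tab$d - d111) < 1e-9))
  # every cubic ring coincident with a hexagonal ring is a common ring
  hex <- hexagonal_ring_table(d_min = 1.5, d_max = 4)
  hex_common <- hex$d[hex$category == "common"]
  cub_common <- tab$d[tab$category == "common"]
  expect_length(cub_common, 3)
  expect_true(all(vapply(cub_common, function(d)
    any(abs(hex_common - d) <= 0.02), TRUE)))
  # the diamond lattice also allows (400) at ~1.59 A, which has no
  # hexagonal counterpart and stays categorized "other"
  other <- tab[tab$category == "other", ]
  expect_equal(nrow(other), 1)
  expect_equal(unname(unlist(other[, c("h", "k", "l")])), c(4, 0, 0))
})

test_that("windows are centred at 1/d, nested, and clip rules hold", {
  tab <- assign_windows(hexagonal_ring_table(), 0.003, 0.010)
  i <- which(abs(tab$d - 3.661) < 1e-3)
  expect_equal(tab$search_lo[i], 1 / tab$d[i] - 0.003)
  expect_equal(tab$search_hi[i], 1 / tab$d[i] + 0.003)
  expect_equal(c(tab$search_lo[i], tab$search_hi[i]), c(0.2702, 0.2762),
               tolerance = 5e-3)
  expect_true(all(tab$search_lo >= tab$interp_lo
                  & tab$search_hi <= tab$interp_hi))
  expect_error(assign_windows(hexagonal_ring_table(), 0.02, 0.01),
               "search_halfwidth")
})

test_that("overlapping interpolation windows merge into one region", {
  tab <- assign_windows(hexagonal_ring_table(), 0.003, 0.010)
  regions <- iceringr:::interp_regions(tab)
  # (200), (112), (201) are close enough that their interp windows merge
  trio <- 1 / tab$d[tab$d < 1.95 & tab$d > 1.88]
  expect_length(trio, 3)
  hits <- vapply(trio, function(s)
    which(s >= regions[, 1] & s <= regions[, 2])[1], 0L)
  expect_equal(length(unique(hits)), 1)
  expect_lt(nrow(regions), nrow(tab))
})

test_that("powder pattern peaks sit at the ring positions", {
  tab <- hexagonal_ring_table()
  grid <- seq(0.24, 0.68, by = 2.5e-4)
  pat <- powder_pattern(tab, grid, width_2theta = 0.05)
  # peak-picking oracle: local maxima above the floor
  y <- pat$intensity
  loc <- which(diff(sign(diff(y))) == -2) + 1
  loc <- loc[y[loc] > max(y) * 1e-3]
  expect_equal(length(loc), 11)
  expect_equal(sort(pat$s[loc]), sort(1 / tab$d), tolerance = 2.6e-4)
})

test_that("powder pattern is linear in scale and F2, and conserves area", {
  tab <- hexagonal_ring_table()[1:1, ]
  grid <- seq(0.2, 0.32, by = 2e-4)
  p1 <- powder_pattern(tab, grid, width_2theta = 0.1)
  expect_lt(abs(p1$s[which.max(p1$intensity)] - 1 / tab$d[1]), 2.1e-4)
  p2 <- powder_pattern(tab, grid, width_2theta = 0.1, scale = 3)
  expect_equal(p2$intensity, 3 * p1$intensity)
  tab2 <- tab; tab2$F2 <- 2 * tab2$F2
  p3 <- powder_pattern(tab2, grid, width_2theta = 0.1)
  expect_equal(sum(p3$intensity), 2 * sum(p1$intensity))
  # integrated intensity is width-independent (unit-area profiles)
  a1 <- sum(p1$intensity) * 2e-4
  a2 <- sum(powder_pattern(tab, grid, width_2theta = 0.05,
                           profile = "gaussian")$intensity) * 2e-4
  expect_equal(a1, a2, tolerance = 0.01)
  expect_error(powder_pattern(tab, grid, wavelength = -1), "wavelength")
  expect_error(powder_pattern(tab, seq(0.2, 3, by = 0.01), wavelength = 0.98),
               "representable")
})

make_mixture <- function(frac, seed, noise = 0.01) {
  grid <- seq(0.245, 0.68, by = 4e-4)
  hex <- powder_pattern(hexagonal_ring_table(d_min = 1.4, d_max = 4.2),
                        grid, width_2theta = 0.12)$intensity
  cub <- powder_pattern(cubic_ring_table(d_min = 1.4, d_max = 4.2),
                        grid, width_2theta = 0.12)$intensity
  ds <- 4e-4
  y <- (1 - frac) * hex / (sum(hex) * ds) + frac * cub / (sum(cub) * ds)
  bg <- 40 + 120 * grid - 90 * grid^2  # smooth instrument background
  withr::with_seed(seed, {
    y <- y + bg + stats::rnorm(length(y), 0, noise * max(y))
  })
  tibble::tibble(s = grid, intensity = y)
}

test_that("mixture fit recovers the cubic fraction on self-generated patterns", {
  for (frac in c(0, 0.5, 1)) {
    fit <- fit_hex_cubic_mixture(make_mixture(frac, seed = 100 + frac * 10))
    expect_lt(abs(fit$cubic_fraction - frac), 0.1,
              label = sprintf("fraction %.2f fitted %.3f", frac,
                              fit$cubic_fraction))
  }
})

test_that("a flat pattern yields the no-ice-signal flag", {
  flat <- tibble::tibble(s = seq(0.25, 0.67, by = 1e-3), intensity = 0)
  fit <- fit_hex_cubic_mixture(flat)
  expect_identical(fit$flag, "no ice signal")
  expect_true(is.na(fit$cubic_fraction))
})

test_that("ring tables export to TSV and re-import", {
  tab <- assign_windows(hexagonal_ring_table())
  path <- tempfile(fileext = ".tsv")
  write_ring_table(tab, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$d, tab$d)
})
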