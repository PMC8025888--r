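# Binned statistics, interpolated expectations and the IFS/DS/OS tracks.

test_that("coarse statistics match hand computation and the sd is population-form", {
  # two coarse bins by construction: s in [0.30, 0.31) and [0.31, 0.32)
  cell <- unit_cell(1000, 1000, 1000)
  # (h,0,0) gives s = h/1000 exactly
  h <- c(301, 303, 305, 312, 314, 316, 318)
  I <- c(1, 2, 6, 10, 10, 16, 4)
  refl <- reflection_set(
    data.frame(h = h, k = 0, l = 0, I = I, sigI = 1), cell
  )
  st <- coarse_stats(refl, width = 0.01)
  expect_equal(st$N, c(3L, 4L))
  expect_equal(st$mean_I, c(3, 10))
  expect_equal(st$sd_I, c(sqrt(mean((c(1, 2, 6) - 3)^2)),
                          sqrt(mean((c(10, 10, 16, 4) - 10)^2))))
  # strict inequality: the two I = 10 records are not below the mean of 10
  expect_equal(st$D, c(2 / 3, 1 / 4))
})

test_that("equal intensities give zero spread and zero below-mean fraction", {
  cell <- unit_cell(1000, 1000, 1000)
  refl <- reflection_set(
    data.frame(h = 300:340, k = 0, l = 0, I = 7, sigI = 1), cell
  )
  st <- coarse_stats(refl)
  occ <- st$N > 0
  expect_true(all(st$sd_I[occ] == 0))
  expect_true(all(st$D[occ] == 0))
})

test_that("binned statistics equal an independent single-pass oracle", {
  refl <- simulate_reflections(5000, seed = 21)
  st <- coarse_stats(refl, width = 0.01)
  # oracle: split records by bin, recompute each statistic directly
  idx <- findInterval(refl$s, st$lo[1], rightmost.closed = FALSE)
  edges <- c(st$lo, st$hi[nrow(st)])
  grp <- cut(refl$s, breaks = edges, right = FALSE, include.lowest = TRUE)
  by_bin <- split(refl$I, grp)
  expect_equal(st$N, unname(lengths(by_bin)))
  occ <- st$N > 0
  expect_equal(st$mean_I[occ], unname(vapply(by_bin[occ], mean, 0)))
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(st$sd_I[occ], unname(vapply(by_bin[occ], sd_pop, 0)))
  D_or <- vapply(by_bin[occ], function(x) mean(x < mean(x)), 0)
  expect_equal(st$D[occ], unname(D_or))
})

test_that("a linear intensity trend is reproduced exactly through a window", {
  # reflections at exact coarse-bin centres, intensities linear in s, all
  # spreads equal: interpolation through the excised window must return the
  # same line, and the constant expectations stay constant after smoothing
  cell <- unit_cell(10000, 10000, 10000)
  h_centres <- seq(2505, 3495, by = 10)  # one cluster per 0.001-wide...
  s_centres <- h_centres / 10000
  recs <- do.call(rbind, lapply(seq_along(h_centres), function(i) {
    data.frame(h = h_centres[i], k = c(0, 1, -1), l = c(0, 1, -1),
               I = 100 + 1000 * s_centres[i] + c(0, 2, -2), sigI = 1)
  }))
  refl <- reflection_set(recs, cell)
  tab <- default_tables()$stage1
  prof <- score_profile(refl, tab)
  # the expected mean track is linear in s across the span of the kept
  # coarse-bin centres, including inside the excised ring windows (outside
  # that span the track is a flagged constant extension)
  co <- coarse_stats(refl, 0.01)
  regions <- iceringr:::interp_regions(tab)
  kept <- co$s[!iceringr:::in_regions(co$s, regions)]
  span <- prof$s >= min(kept) & prof$s <= max(kept)
  fit <- stats::lm(mu ~ s, data = prof[span, ])
  expect_lt(max(abs(stats::resid(fit))), 1e-8)
  expect_equal(unname(stats::coef(fit)[2]), 1000, tolerance = 1e-6)
  in_window <- span & !prof$off_window
  expect_true(any(in_window))
  expect_equal(prof$mu[in_window],
               unname(stats::predict(fit, prof[in_window, ])))
  # constant sd track stays constant after interpolation + smoothing
  expect_lt(diff(range(prof$sigma[span])), 1e-8)
})

test_that("expectations match an independently coded interpolate-then-smooth oracle", {
  refl <- simulate_reflections(20000, seed = 31)
  tab <- default_tables()$stage1
  prof <- score_profile(refl, tab)
  exps <- interpolate_expectations(refl, tab)
  expect_equal(exps$f, prof$f)

  # oracle: coarse bins, drop windowed bins, approx() + explicit Gaussian kernel
  co <- coarse_stats(refl, 0.01)
  regions <- iceringr:::interp_regions(tab)
  off <- !iceringr:::in_regions(co$s, regions)
  use <- off & co$N >= 3 & co$sd_I > 0
  mu_or <- stats::approx(co$s[use], co$mean_I[use], prof$s, rule = 2)$y
  sd_or <- stats::approx(co$s[use], co$sd_I[use], prof$s, rule = 2)$y
  ratio <- mu_or / sd_or
  sm <- vapply(seq_along(ratio), function(i) {
    w <- stats::dnorm(prof$s - prof$s[i], sd = 0.01)
    w[abs(prof$s - prof$s[i]) > 4 * 0.01 + 1e-12] <- 0
    sum(w * ratio) / sum(w)
  }, 0)
  expect_equal(prof$mu, mu_or, tolerance = 1e-10)
  expect_equal(prof$f, sm, tolerance = 1e-10)
})

test_that("null profiles have centred unit-ish score tracks", {
  tab <- default_tables()$stage1
  for (seed in c(61, 62, 63)) {
    prof <- score_profile(simulate_reflections(20000, seed = seed), tab)
    off <- prof$off_window
    expect_lt(abs(mean(prof$IFS[off], na.rm = TRUE)), 0.1)
    expect_true(dplyr::between(sd(prof$IFS[off], na.rm = TRUE), 0.7, 1.4))
    expect_lt(abs(mean(prof$DS[off], na.rm = TRUE)), 0.1)
    expect_equal(sd(prof$DS[off], na.rm = TRUE), 1, tolerance = 1e-6)
    expect_lt(abs(mean(prof$OS[off], na.rm = TRUE)), 0.15)
  }
})

test_that("bias injected at a ring drives IFS and DS above the off-window tail", {
  tab <- default_tables()$stage1
  ring110 <- tab[tab$h == 1 & tab$k == 1 & tab$l == 0, ]
  refl <- inject_ice_bias(simulate_reflections(20000, seed = 71), ring110, 2)
  prof <- score_profile(refl, tab)
  win <- prof$s >= ring110$search_lo & prof$s <= ring110$search_hi
  q99_ifs <- quantile(prof$IFS[prof$off_window], 0.99, na.rm = TRUE)
  expect_gt(max(prof$IFS[win], na.rm = TRUE), q99_ifs)
  expect_gt(max(prof$DS[win], na.rm = TRUE), 0)
})

test_that("score tracks are invariant to global rescale and record order", {
  tab <- default_tables()$stage1
  refl <- simulate_reflections(10000, seed = 81)
  prof <- score_profile(refl, tab)
  scaled <- refl
  scaled$I <- scaled$I * 17
  scaled$sigI <- scaled$sigI * 17
  prof_s <- score_profile(scaled, tab)
  expect_equal(prof_s$IFS, prof$IFS)
  expect_equal(prof_s$DS, prof$DS)
  expect_equal(prof_s$OS, prof$OS)
  perm <- refl[sample(nrow(refl)), ]
  attr(perm, "cell") <- attr(refl, "cell")
  prof_p <- score_profile(perm, tab)
  expect_equal(prof_p$IFS, prof$IFS)
})

test_that("missing reflections raise OS monotonically with the removed fraction", {
  tab <- default_tables()$stage1
  ring <- tab[1, ]
  base <- simulate_reflections(20000, seed = 91)
  os_at <- function(fraction) {
    refl <- inject_exclusions(base, ring, fraction, window = "search",
                              seed = 91)
    prof <- score_profile(refl, tab)
    win <- prof$s >= ring$search_lo & prof$s <= ring$search_hi
    max(prof$OS[win], na.rm = TRUE)
  }
  os <- vapply(c(0, 0.5, 1), os_at, 0)
  expect_lt(os[1], 3)
  expect_gt(os[3], 5)
  expect_true(all(diff(os) > 0))
})

test_that("degenerate intensity distributions are rejected", {
  cell <- unit_cell(1000, 1000, 1000)
  refl <- reflection_set(
    data.frame(h = 250:556, k = 0, l = 0, I = 5, sigI = 1), cell
  )
  expect_error(score_profile(refl, default_tables()$stage1),
               "degenerate|zero|fewer than two")
})
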