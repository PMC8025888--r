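# GEV nulls, ICS condensation, calibration and two-stage classification.

test_that("GEV functions satisfy the Gumbel closed forms and monotonicity", {
  expect_equal(p_upper(2, list(loc = 2, scale = 1, shape = 0)),
               1 - exp(-1), tolerance = 1e-12)
  x <- seq(-3, 8, by = 0.25)
  p <- p_upper(x, list(loc = 0.5, scale = 1.2, shape = 0.1))
  expect_true(all(diff(p) < 0))
  # density integrates to one
  for (shape in c(-0.2, 0, 0.3)) {
    integ <- integrate(dgev, -Inf, Inf, loc = 1, scale = 2, shape = shape,
                       rel.tol = 1e-9)
    expect_equal(integ$value, 1, tolerance = 1e-6)
  }
  # quantile inverts the CDF
  expect_equal(pgev(qgev(0.3, 1, 2, 0.2), 1, 2, 0.2), 0.3)
})

test_that("GEV maximum likelihood recovers known parameters", {
  true <- list(loc = 1.5, scale = 0.8, shape = 0.15)
  x <- withr::with_seed(99, qgev(runif(2000), true$loc, true$scale,
                                 true$shape))
  fit <- fit_gev(x)
  expect_equal(fit$loc, true$loc, tolerance = 0.1)
  expect_equal(fit$scale, true$scale, tolerance = 0.1)
  expect_error(fit_gev(rnorm(10)), "at least 50")
})

test_that("ring weights implement the ice-to-protein intensity ratio", {
  tab <- default_tables()$stage1
  w <- ring_weight(tab$m, tab$F2, tab$d)
  # independent transcription, symbol by symbol
  w_or <- tab$m * tab$F2 * exp((35 - 1.5) / (2 * tab$d^2))
  expect_equal(w, w_or)
  # detection capacity grows with resolution: (112) beats (002)
  expect_gt(w[tab$l == 2 & tab$h == 1], w[tab$h == 0])
  # equal B factors cancel the exponential
  w_eq <- ring_weight(tab$m, tab$F2, tab$d, b_ice = 35, b_protein = 35)
  expect_equal(w_eq, tab$m * tab$F2)
  # fixed m*F2: weights strictly increase from (002) to (110) to (112)
  w_fixed <- ring_weight(1, 1, sort(tab$d, decreasing = TRUE))
  expect_true(all(diff(w_fixed) > 0))
})

test_that("per-ring ICS combines windowed maxima as a weighted average", {
  tab <- default_tables()$stage1[1, ]
  prof <- tibble::tibble(
    s = seq(tab$search_lo - 0.002, tab$search_hi + 0.002, by = 0.001),
    IFS = 0, DS = 0
  )
  prof$IFS[4] <- 2
  prof$DS[5] <- 4
  expect_equal(ring_ics(prof, tab, w_ifs = 1, w_ds = 1)$ics, 3)
  expect_equal(ring_ics(prof, tab, w_ifs = 1, w_ds = 0)$ics, 2)
  expect_equal(ring_ics(prof, tab, w_ifs = 0, w_ds = 1)$ics, 4)
})

test_that("Glass effect size matches its definition", {
  expect_equal(glass_effect_size(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(glass_effect_size(rep(2, 5), c(0, 1, 2)), 1)
  a <- withr::with_seed(7, rnorm(40, 3))
  b <- withr::with_seed(8, rnorm(60, 1))
  expect_equal(glass_effect_size(a, b), (mean(a) - mean(b)) / sd(b),
               tolerance = 1e-12)
  expect_error(glass_effect_size(1:3, c(2, 2, 2)), "zero spread")
})

test_that("combined ICS is a weighted mean over available rings", {
  expect_equal(combined_ics(5, 2), 5)
  expect_equal(combined_ics(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(combined_ics(c(1, NA, 3), c(1, 1, 1)), 2)
  expect_true(is.na(combined_ics(NA_real_, 1)))
})

test_that("data truncated at 2 A drops the (112) ring from scoring", {
  tabs <- default_tables()
  refl <- simulate_reflections(15000, d_min = 2.0, seed = 41)
  smry <- ice_set_summary(refl, tabs, stage2 = FALSE)
  expect_equal(nrow(smry$stage1), 2)
  expect_true(all(smry$stage1$d > 2))
})

test_that("null ICS distribution is right-skewed", {
  tabs <- default_tables()
  cell <- synthetic_cell(8000, 1.8, 30)
  pool <- reflection_pool(cell, 1.8, 30)
  ics <- unlist(lapply(1:60, function(i) {
    refl <- simulate_reflections(8000, seed = 3000 + i, cell = cell,
                                 pool = pool)
    smry <- ice_set_summary(refl, tabs, stage2 = FALSE)
    iceringr:::.set_ics(smry$stage1, 1, 1)$rings$ics
  }))
  skew <- mean((ics - mean(ics))^3) / sd(ics)^3
  expect_gt(skew, 0)
})

test_that("calibration produces sane weights, nulls and thresholds", {
  calib <- small_calibration()
  expect_gt(calib$w_ifs, 0)
  expect_gt(calib$w_ds, 0)
  expect_gt(calib$gev_ics$scale, 0)
  expect_gt(calib$gev_os$scale, 0)
  expect_true(calib$p_ice_threshold > 0 && calib$p_ice_threshold < 1)
  expect_equal(nrow(calib$stage2_quantiles), 3)
  # single-class training falls back to equal weights with a flag
  tr <- synthetic_training(n_sets = 60, frac_ice = 0, n_reflections = 6000,
                           seed = 77, stage2 = FALSE)
  calib0 <- calibrate_ice(tr$summaries, tr$labels)
  expect_equal(calib0$w_ifs, calib0$w_ds)
  expect_true("equal-weights-fallback" %in% calib0$flags)
  expect_equal(calib0$p_ice_threshold, 0.006)
  expect_equal(calib0$p_obs_threshold, 0.00005)
})

test_that("classification follows the two-stage decision rules", {
  tabs <- default_tables()
  calib <- small_calibration()
  mk <- function(seed) simulate_reflections(20000, seed = seed)

  expect_identical(classify_ice(mk(101), calib, tabs)$classification,
                   "no_ice")
  r_sd <- inject_ice_bias(mk(102), tabs$stage1, 2)
  expect_identical(classify_ice(r_sd, calib, tabs)$classification,
                   "stacking_disordered")
  r_hex <- inject_ice_bias(inject_ice_bias(mk(103), tabs$stage1, 2),
                           tabs$stage2, 2)
  expect_identical(classify_ice(r_hex, calib, tabs)$classification,
                   "hexagonal")
  r_exc <- inject_exclusions(mk(104), tabs$stage1, 1, seed = 104)
  expect_identical(classify_ice(r_exc, calib, tabs)$classification,
                   "excluded_regions")
})

test_that("admission rules gate the report", {
  calib <- small_calibration()
  small <- simulate_reflections(3000, seed = 105)
  expect_identical(classify_ice(small, calib)$classification,
                   "insufficient_data")
  low_res <- simulate_reflections(6000, d_min = 3.8, d_max = 40, seed = 106)
  expect_identical(classify_ice(low_res, calib)$classification,
                   "insufficient_data")
})

test_that("classification is invariant to intensity scale and record order", {
  tabs <- default_tables()
  calib <- small_calibration()
  refl <- inject_ice_bias(simulate_reflections(12000, seed = 111),
                          tabs$stage1, 1.5)
  rep1 <- classify_ice(refl, calib, tabs)
  scaled <- refl
  scaled$I <- scaled$I * 0.01
  scaled$sigI <- scaled$sigI * 0.01
  rep2 <- classify_ice(scaled, calib, tabs)
  expect_identical(rep2$classification, rep1$classification)
  expect_equal(rep2$p_ice, rep1$p_ice)
  perm <- refl[rev(seq_len(nrow(refl))), ]
  attr(perm, "cell") <- attr(refl, "cell")
  rep3 <- classify_ice(perm, calib, tabs)
  expect_equal(rep3$p_ice, rep1$p_ice)
})

test_that("reports and calibrations round-trip through JSON", {
  tabs <- default_tables()
  calib <- small_calibration()
  refl <- inject_ice_bias(simulate_reflections(12000, seed = 121),
                          tabs$stage1, 2)
  report <- classify_ice(refl, calib, tabs)
  path <- tempfile(fileext = ".json")
  write_ice_report(report, path)
  back <- read_ice_report(path)
  expect_identical(back$classification, report$classification)
  expect_equal(back$p_ice, report$p_ice)
  expect_equal(tibble::as_tibble(back$rings), report$rings)

  cpath <- tempfile(fileext = ".json")
  write_ice_calibration(calib, cpath)
  cback <- read_ice_calibration(cpath)
  expect_equal(cback$w_ifs, calib$w_ifs)
  expect_equal(cback$gev_ics$loc, calib$gev_ics$loc)
  expect_equal(cback$p_ice_threshold, calib$p_ice_threshold)
  r2 <- classify_ice(refl, cback, tabs)
  expect_equal(r2$p_ice, report$p_ice)
})

test_that("tidy and glance methods summarize reports and fits", {
  calib <- small_calibration()
  refl <- inject_ice_bias(simulate_reflections(12000, seed = 131),
                          default_tables()$stage1, 2)
  report <- classify_ice(refl, calib)
  td <- tidy(report)
  expect_true(all(c("max_ifs", "max_ds", "ics", "stage") %in% names(td)))
  gl <- glance(report)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$classification, report$classification)
  expect_equal(nrow(tidy(calib)), 2)
  expect_equal(glance(calib)$w_ifs, calib$w_ifs)
  expect_equal(tidy(calib$gev_ics)$estimate[1], calib$gev_ics$loc)
})
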