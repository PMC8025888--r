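# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_tables <- function() fixture("tables", ice_detection_tables)

# A small calibration shared by the classification tests (not the
# acceptance-scale one).
small_calibration <- function() {
  fixture("small_calib", function() {
    tr <- synthetic_training(n_sets = 120, frac_ice = 0.25,
                             frac_excluded = 0.1, n_reflections = 8000,
                             seed = 11)
    calibrate_ice(tr$summaries, tr$labels)
  })
}

# Write a plain reflection table with a cell header; returns the path.
write_table_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("refl", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}

# Brute-force d-spacing oracle: build the direct basis vectors explicitly,
# form the reciprocal basis by cross products, and take |h a* + k b* + l c*|^-1.
d_spacing_oracle <- function(a, b, c, alpha, beta, gamma, hkl) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  av <- c(a, 0, 0)
  bv <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(c^2 - cx^2 - cy^2)
  cv <- c(cx, cy, cz)
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  vol <- sum(av * cross(bv, cv))
  as <- cross(bv, cv) / vol
  bs <- cross(cv, av) / vol
  cs <- cross(av, bv) / vol
  g <- hkl[1] * as + hkl[2] * bs + hkl[3] * cs
  1 / sqrt(sum(g^2))
}

# The labelled 500-set training population used by the detection-rate
# checks: 80% clean, 20% with common-ring bias of amplitude log-uniform in
# [0.5, 4]; 20000 reflections per set, d_min = 1.8 A, B_protein = 35 A^2.
acceptance_t7 <- function() {
  fixture("acc_t7", function() {
    tr <- synthetic_training(n_sets = 500, frac_ice = 0.2,
                             amplitude_range = c(0.5, 4),
                             n_reflections = 20000, d_min = 1.8,
                             b_protein = 35, stage2 = TRUE, seed = 1)
    calib <- calibrate_ice(tr$summaries, tr$labels)
    list(training = tr, calibration = calib,
         evaluation = evaluate_detection(tr$summaries, tr$labels, calib))
  })
}
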