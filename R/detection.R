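# Condensing score tracks into per-ring Ice Contamination Scores, combining
# them with resolution-dependent weights, calibrating GEV null
# distributions, and classifying data sets.

#' Ring tables used by the two detection stages
#'
#' Stage 1 scores the three rings common to all ice forms — (002), (110),
#' (112) — which stacking disorder does not broaden. Stage 2, run only on
#' sets flagged for ice, re-scores at the hexagonal-only (101), (102) and
#' (103) positions, which are strongly suppressed in stacking-disordered
#' ice; detection there implies hexagonal ice.
#'
#' @param hex_cell,cubic_cell Reference cells.
#' @param search_halfwidth,interp_halfwidth Window half-widths in 1/Angstrom.
#' @return List with `stage1`, `stage2` and `full` ring tables (windowed).
#' @export
ice_detection_tables <- function(hex_cell = ice_cells()$hex,
                                 cubic_cell = ice_cells()$cubic,
                                 search_halfwidth = 0.003,
                                 interp_halfwidth = 0.010) {
  full <- assign_windows(
    hexagonal_ring_table(hex_cell, d_min = 1.5, d_max = 4,
                         cubic_cell = cubic_cell),
    search_halfwidth, interp_halfwidth
  )
  key <- paste(full$h, full$k, full$l)
  list(
    stage1 = full[full$category == "common", ],
    stage2 = full[key %in% c("1 0 1", "1 0 2", "1 0 3"), ],
    full = full
  )
}

#' Resolution-dependent ring weight
#'
#' \deqn{\omega_{hkl} = m F^2 \exp[(B_{protein} - B_{ice}) / (2 d^2)],}
#' the Wilson-statistics ratio of ice to protein diffraction intensity at
#' the ring: protein diffraction falls off much faster with resolution
#' (B_protein >> B_ice), so ice biasing is easier to detect at higher
#' resolution and those rings earn more weight.
#'
#' @param m Ring multiplicity.
#' @param F2 Squared structure factor.
#' @param d Ring resolution in Angstrom.
#' @param b_ice,b_protein Wilson B factors in Angstrom^2.
#' @return Positive weight(s).
#' @export
ring_weight <- function(m, F2, d, b_ice = 1.5, b_protein = 35) {
  stopifnot(b_protein > 0, b_ice > 0)
  m * F2 * exp((b_protein - b_ice) / (2 * d^2))
}

#' Glass's effect size
#'
#' Difference of group means normalized by the control-group standard
#' deviation: Delta = (mean(with) - mean(without)) / sd(without). Used to
#' weight the IFS and DS contributions to the ICS by how well each
#' separates icy from ice-free training sets.
#'
#' @param with_ice,without_ice Numeric score samples.
#' @return The effect size.
#' @export
glass_effect_size <- function(with_ice, without_ice) {
  without_ice <- without_ice[is.finite(without_ice)]
  with_ice <- with_ice[is.finite(with_ice)]
  if (length(without_ice) < 2) {
    stop("control sample needs at least two values", call. = FALSE)
  }
  s0 <- stats::sd(without_ice)
  if (s0 == 0) stop("control sample has zero spread", call. = FALSE)
  (mean(with_ice) - mean(without_ice)) / s0
}

# Per-ring windowed score maxima for the rings of `table` visible in the
# profile's s range.
.ring_maxima <- function(profile, table) {
  purrr::map_dfr(seq_len(nrow(table)), function(i) {
    inside <- profile$s >= table$search_lo[i] & profile$s <= table$search_hi[i]
    ifs <- profile$IFS[inside]; ds <- profile$DS[inside]
    if (!any(inside) || all(!is.finite(ifs))) {
      return(tibble::tibble())
    }
    tibble::tibble(
      h = table$h[i], k = table$k[i], l = table$l[i],
      d = table$d[i], m = table$m[i], F2 = table$F2[i],
      max_ifs = max(ifs, na.rm = TRUE),
      max_ds = if (any(is.finite(ds))) max(ds, na.rm = TRUE) else NA_real_
    )
  })
}

#' Per-ring Ice Contamination Score
#'
#' ICS = (w_ifs max IFS + w_ds max DS) / (w_ifs + w_ds), the weighted
#' average of the windowed maxima of the two biasing scores at one ring.
#' The maximum over the search window absorbs small variations in the true
#' ice-ring position; being a maximum of a few bins, its null distribution
#' is approximately generalized extreme value.
#'
#' @param profile An `ice_score_profile`.
#' @param table Ring table (rows = rings to score).
#' @param w_ifs,w_ds Nonnegative score weights; `w_ifs + w_ds > 0`.
#' @return Tibble with one row per scoreable ring: hkl, d, m, F2, max_ifs,
#'   max_ds, ics.
#' @export
ring_ics <- function(profile, table, w_ifs = 1, w_ds = 1) {
  stopifnot(w_ifs >= 0, w_ds >= 0, w_ifs + w_ds > 0)
  mx <- .ring_maxima(profile, table)
  if (!nrow(mx)) return(mx)
  ds_term <- ifelse(is.finite(mx$max_ds), mx$max_ds, 0)
  w_ds_eff <- ifelse(is.finite(mx$max_ds), w_ds, 0)
  mx$ics <- (w_ifs * mx$max_ifs + w_ds_eff * ds_term) /
    (w_ifs + w_ds_eff)
  mx
}

#' Combined weighted-average ICS
#'
#' @param ics Per-ring ICS values.
#' @param weights Per-ring weights (see [ring_weight()]).
#' @return The weighted mean; NA when no rings are available.
#' @export
combined_ics <- function(ics, weights) {
  ok <- is.finite(ics) & is.finite(weights)
  if (!any(ok)) return(NA_real_)
  sum(ics[ok] * weights[ok]) / sum(weights[ok])
}

#' Observation-score summary
#'
#' Mean OS over each common ring's interpolation region; the summary
#' statistic <OS> is the maximum of the region means, so exclusion of even
#' a single ring region drives it.
#'
#' @param profile An `ice_score_profile`.
#' @param table Common-ring table with interpolation windows.
#' @return List with `regions` (tibble: hkl, d, mean_os, n_bins) and
#'   `os_max`.
#' @export
obs_summary <- function(profile, table) {
  regions <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    inside <- profile$s >= table$interp_lo[i] & profile$s <= table$interp_hi[i]
    os <- profile$OS[inside]
    if (!any(is.finite(os))) return(tibble::tibble())
    tibble::tibble(h = table$h[i], k = table$k[i], l = table$l[i],
                   d = table$d[i], mean_os = mean(os, na.rm = TRUE),
                   n_bins = sum(is.finite(os)))
  })
  list(regions = regions,
       os_max = if (nrow(regions)) max(regions$mean_os) else NA_real_)
}

#' Per-set summary statistics for calibration and classification
#'
#' Runs the scoring pipeline on one reflection set and condenses it to the
#' small set of statistics the calibration needs: per-ring windowed maxima
#' of IFS and DS at the stage-1 (common) and optionally stage-2
#' (hexagonal-only) rings, the OS region means, and admission quantities.
#'
#' @param refl A [reflection_set()].
#' @param tables From [ice_detection_tables()].
#' @param stage2 Also score the hexagonal-only rings?
#' @return An `ice_set_summary` list.
#' @export
ice_set_summary <- function(refl, tables = ice_detection_tables(),
                            stage2 = TRUE) {
  prof1 <- score_profile(refl, tables$stage1)
  os <- obs_summary(prof1, tables$stage1)
  out <- list(
    stage1 = .ring_maxima(prof1, tables$stage1),
    os_regions = os$regions,
    os_max = os$os_max,
    n_reflections = nrow(refl),
    d_min = min(refl$d),
    flags = attr(prof1, "flags"),
    source_label = attr(refl, "source_label")
  )
  if (stage2) {
    prof2 <- try(score_profile(refl, tables$stage2), silent = TRUE)
    out$stage2 <- if (inherits(prof2, "try-error")) {
      tibble::tibble()
    } else {
      .ring_maxima(prof2, tables$stage2)
    }
  }
  structure(out, class = "ice_set_summary")
}

.set_ics <- function(stage_tbl, w_ifs, w_ds, b_ice = 1.5, b_protein = 35) {
  if (!nrow(stage_tbl)) {
    return(list(rings = stage_tbl, combined = NA_real_))
  }
  ds_term <- ifelse(is.finite(stage_tbl$max_ds), stage_tbl$max_ds, 0)
  w_ds_eff <- ifelse(is.finite(stage_tbl$max_ds), w_ds, 0)
  stage_tbl$ics <- (w_ifs * stage_tbl$max_ifs + w_ds_eff * ds_term) /
    (w_ifs + w_ds_eff)
  stage_tbl$weight <- ring_weight(stage_tbl$m, stage_tbl$F2, stage_tbl$d,
                                  b_ice, b_protein)
  list(rings = stage_tbl,
       combined = combined_ics(stage_tbl$ics, stage_tbl$weight))
}

# Largest threshold tau (flag when p <= tau) whose empirical
# false-discovery rate among flagged training sets stays at or below `fdr`.
# The empirical FDR is a step function jumping at observed p values, so the
# supremum of admissible thresholds lies just below the next failing
# candidate; the midpoint between the largest passing candidate and the next
# one keeps the training flags identical while leaving headroom for new data.
.fdr_threshold <- function(p, is_positive, fdr, default) {
  ok <- is.finite(p)
  p <- p[ok]; is_positive <- is_positive[ok]
  if (!any(is_positive) || all(is_positive)) return(default)
  cand <- sort(unique(p))
  rate <- vapply(cand, function(tau) {
    flagged <- p <= tau
    sum(flagged & !is_positive) / sum(flagged)
  }, 0)
  pass <- which(rate <= fdr)
  if (!length(pass)) return(min(cand) / 2)
  i <- max(pass)
  if (i < length(cand)) (cand[i] + cand[i + 1]) / 2 else cand[i]
}

#' Calibrate the detection null distributions and weights
#'
#' From per-set summaries ([ice_set_summary()]) with training labels:
#' \itemize{
#'   \item omega_IFS and omega_DS from Glass effect sizes of the per-set
#'     maximum IFS and DS between icy and clean sets (equal weights, with a
#'     flag, when only one class is present);
#'   \item GEV nulls for <ICS> and <OS> fitted to the clean subset;
#'   \item p-value thresholds chosen as the largest threshold with empirical
#'     training false-discovery rate at or below `fdr_ice` (default 5%) and
#'     `fdr_obs` (default 0.5%), falling back to 0.006 / 0.00005 when the
#'     training set cannot estimate them;
#'   \item per-ring null ICS quantiles (level matching the p_ice threshold)
#'     for the stage-2 hexagonal-only rings.
#' }
#'
#' @param summaries List of `ice_set_summary` objects.
#' @param labels Character vector: "clean", "ice" (intensity bias) or
#'   "excluded" (reflections removed at the rings).
#' @param b_ice,b_protein Wilson B factors for the ring weights.
#' @param fdr_ice,fdr_obs Training FDR targets.
#' @param default_p_ice,default_p_obs Fallback thresholds.
#' @return An `ice_calibration` object.
#' @export
calibrate_ice <- function(summaries, labels, b_ice = 1.5, b_protein = 35,
                          fdr_ice = 0.05, fdr_obs = 0.005,
                          default_p_ice = 0.006, default_p_obs = 0.00005) {
  stopifnot(length(summaries) == length(labels))
  labels <- match.arg(labels, c("clean", "ice", "excluded"),
                      several.ok = TRUE)
  clean <- labels == "clean"
  if (sum(clean) < 50) {
    stop("need at least 50 clean training sets for the GEV null",
         call. = FALSE)
  }
  flags <- character()

  max_ifs <- vapply(summaries, function(x)
    if (nrow(x$stage1)) max(x$stage1$max_ifs, na.rm = TRUE) else NA_real_, 0)
  max_ds <- vapply(summaries, function(x)
    if (nrow(x$stage1)) suppressWarnings(max(x$stage1$max_ds, na.rm = TRUE))
    else NA_real_, 0)
  max_ds[!is.finite(max_ds)] <- NA_real_

  if (any(labels == "ice")) {
    w_ifs <- max(glass_effect_size(max_ifs[labels == "ice"], max_ifs[clean]),
                 0)
    w_ds <- max(glass_effect_size(max_ds[labels == "ice"], max_ds[clean]), 0)
    if (w_ifs + w_ds == 0) {
      w_ifs <- w_ds <- 1
      flags <- c(flags, "equal-weights-fallback")
    }
  } else {
    w_ifs <- w_ds <- 1
    flags <- c(flags, "equal-weights-fallback")
  }

  ics_all <- vapply(summaries, function(x)
    .set_ics(x$stage1, w_ifs, w_ds, b_ice, b_protein)$combined, 0)
  os_all <- vapply(summaries, function(x) x$os_max %||% NA_real_, 0)

  gev_ics <- fit_gev(ics_all[clean])
  gev_os <- fit_gev(os_all[clean])
  p_ice <- p_upper(ics_all, gev_ics)
  p_obs <- p_upper(os_all, gev_os)

  thr_ice <- if (any(labels == "ice")) {
    .fdr_threshold(p_ice, labels == "ice", fdr_ice, default_p_ice)
  } else {
    default_p_ice
  }
  thr_obs <- if (any(labels == "excluded")) {
    .fdr_threshold(p_obs, labels == "excluded", fdr_obs, default_p_obs)
  } else {
    default_p_obs
  }

  # Stage-2 per-ring null quantiles at the level implied by thr_ice.
  q_level <- 1 - thr_ice
  stage2_null <- purrr::map_dfr(summaries[clean], function(x) {
    if (is.null(x$stage2) || !nrow(x$stage2)) return(tibble::tibble())
    .set_ics(x$stage2, w_ifs, w_ds, b_ice, b_protein)$rings
  })
  stage2_q <- if (nrow(stage2_null)) {
    dplyr::summarise(
      dplyr::group_by(stage2_null, .data$h, .data$k, .data$l, .data$d),
      q_null = stats::quantile(.data$ics, q_level, type = 8, na.rm = TRUE),
      n = sum(is.finite(.data$ics)), .groups = "drop"
    )
  } else {
    tibble::tibble()
  }

  structure(list(
    w_ifs = w_ifs, w_ds = w_ds,
    gev_ics = gev_ics, gev_os = gev_os,
    p_ice_threshold = thr_ice, p_obs_threshold = thr_obs,
    stage2_quantiles = stage2_q,
    b_ice = b_ice, b_protein = b_protein,
    n_training = length(summaries), n_clean = sum(clean),
    flags = flags
  ), class = "ice_calibration")
}

#' @export
print.ice_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "<ice_calibration> %d training sets (%d clean)\n",
    "  weights: w_IFS=%.3f w_DS=%.3f\n",
    "  <ICS> null GEV: loc=%.3f scale=%.3f shape=%.3f\n",
    "  <OS>  null GEV: loc=%.3f scale=%.3f shape=%.3f\n",
    "  thresholds: p_ice=%g p_obs=%g\n"),
    x$n_training, x$n_clean, x$w_ifs, x$w_ds,
    x$gev_ics$loc, x$gev_ics$scale, x$gev_ics$shape,
    x$gev_os$loc, x$gev_os$scale, x$gev_os$shape,
    x$p_ice_threshold, x$p_obs_threshold))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a labelled synthetic training population
#'
#' Default mix: `frac_ice` of the sets carry additive ring bias at the
#' common rings with amplitude log-uniform in `amplitude_range`;
#' `frac_excluded` have all reflections removed inside the common-ring
#' search windows; the rest are clean.
#'
#' @param n_sets Number of sets.
#' @param frac_ice,frac_excluded Class fractions.
#' @param amplitude_range Bias amplitude range (log-uniform draw).
#' @param exclusion_fraction Removal fraction for the excluded class.
#' @param n_reflections,d_min,d_max,b_protein Passed to
#'   [simulate_reflections()].
#' @param tables Detection tables.
#' @param stage2 Score stage-2 rings too?
#' @param seed Integer seed.
#' @return List with `summaries`, `labels`, `amplitudes`.
#' @export
synthetic_training <- function(n_sets = 500, frac_ice = 0.2,
                               frac_excluded = 0, amplitude_range = c(0.5, 4),
                               exclusion_fraction = 1,
                               n_reflections = 20000, d_min = 1.8,
                               d_max = 30, b_protein = 35,
                               tables = ice_detection_tables(),
                               stage2 = TRUE, seed = 1) {
  n_ice <- round(frac_ice * n_sets)
  n_exc <- round(frac_excluded * n_sets)
  labels <- rep(c("clean", "ice", "excluded"),
                c(n_sets - n_ice - n_exc, n_ice, n_exc))
  cell <- synthetic_cell(n_reflections, d_min, d_max)
  pool <- reflection_pool(cell, d_min, d_max)
  amplitudes <- rep(NA_real_, n_sets)
  amp_draw <- withr::with_seed(seed, exp(stats::runif(
    n_sets, log(amplitude_range[1]), log(amplitude_range[2]))))
  summaries <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    set_seed <- (seed * 10007L + i) %% .Machine$integer.max
    refl <- simulate_reflections(n_reflections, d_min, d_max,
                                 b_protein = b_protein, seed = set_seed,
                                 cell = cell, pool = pool)
    if (labels[i] == "ice") {
      amplitudes[i] <- amp_draw[i]
      refl <- inject_ice_bias(refl, tables$stage1, amplitudes[i])
    } else if (labels[i] == "excluded") {
      refl <- inject_exclusions(refl, tables$stage1, exclusion_fraction,
                                window = "search", seed = set_seed)
    }
    summaries[[i]] <- ice_set_summary(refl, tables, stage2 = stage2)
  }
  list(summaries = summaries, labels = labels, amplitudes = amplitudes)
}

#' Detect and classify ice contamination in a reflection set
#'
#' The full two-stage procedure. Admission first: sets with fewer than 5000
#' reflections or with no data at the lowest detection ring (d_min above
#' 3.661 Angstrom) are reported as `insufficient_data` — the metrics are too
#' noisy there. Stage 1 computes <ICS> at the common rings and its upper-tail
#' p-value p_ice under the calibrated GEV null; a set below the threshold is
#' flagged for ice. Flagged sets are re-scored at the hexagonal-only rings:
#' detection at any of them (ICS above that ring's null quantile) means
#' `hexagonal` ice, none means `stacking_disordered`. Unflagged sets with
#' p_obs (from <OS>) below its threshold are `excluded_regions` — the ice
#' was handled by throwing away the ring shells; otherwise `no_ice`.
#'
#' @param refl A [reflection_set()].
#' @param calibration An [calibrate_ice()] result.
#' @param tables Detection tables (must match the calibration's).
#' @return An `ice_report` object.
#' @export
classify_ice <- function(refl, calibration,
                         tables = ice_detection_tables()) {
  stopifnot(inherits(calibration, "ice_calibration"))
  base <- list(
    source_label = attr(refl, "source_label"),
    n_reflections = nrow(refl),
    d_min = min(refl$d),
    flags = attr(refl, "flags") %||% character()
  )
  if (base$n_reflections < 5000 || base$d_min > 3.661) {
    return(structure(c(base, list(classification = "insufficient_data")),
                     class = "ice_report"))
  }
  smry <- ice_set_summary(refl, tables, stage2 = TRUE)
  s1 <- .set_ics(smry$stage1, calibration$w_ifs, calibration$w_ds,
                 calibration$b_ice, calibration$b_protein)
  if (!is.finite(s1$combined)) {
    return(structure(c(base, list(classification = "insufficient_data")),
                     class = "ice_report"))
  }
  p_ice <- p_upper(s1$combined, calibration$gev_ics)
  p_obs <- if (is.finite(smry$os_max)) {
    p_upper(smry$os_max, calibration$gev_os)
  } else {
    NA_real_
  }

  stage2_detail <- tibble::tibble()
  if (p_ice <= calibration$p_ice_threshold) {
    s2 <- .set_ics(smry$stage2, calibration$w_ifs, calibration$w_ds,
                   calibration$b_ice, calibration$b_protein)$rings
    if (nrow(s2) && nrow(calibration$stage2_quantiles)) {
      s2 <- dplyr::left_join(s2, calibration$stage2_quantiles,
                             by = c("h", "k", "l", "d"))
      s2$detected <- is.finite(s2$q_null) & s2$ics > s2$q_null
      stage2_detail <- s2
      classification <- if (any(s2$detected)) "hexagonal" else
        "stacking_disordered"
    } else {
      classification <- "stacking_disordered"
    }
  } else if (is.finite(p_obs) && p_obs <= calibration$p_obs_threshold) {
    classification <- "excluded_regions"
  } else {
    classification <- "no_ice"
  }

  structure(c(base, list(
    rings = s1$rings,
    combined_ics = s1$combined,
    p_ice = p_ice,
    os_regions = smry$os_regions,
    os_max = smry$os_max,
    p_obs = p_obs,
    stage2 = stage2_detail,
    classification = classification,
    flags = union(base$flags, smry$flags)
  )), class = "ice_report")
}

#' @export
print.ice_report <- function(x, ...) {
  cat(sprintf("<ice_report> %s: %s\n", x$source_label %||% "data set",
              x$classification))
  if (!is.null(x$p_ice)) {
    cat(sprintf("  <ICS>=%.3f p_ice=%.4g   <OS>=%.3f p_obs=%.4g\n",
                x$combined_ics, x$p_ice, x$os_max, x$p_obs))
  }
  cat(sprintf("  %d reflections, d_min %.3f A\n", x$n_reflections, x$d_min))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate detection over a labelled population
#'
#' Applies a calibration to per-set summaries and reports, per set, the
#' combined scores, p-values and threshold flags — the raw material for
#' false-discovery-rate, sensitivity and specificity estimates.
#'
#' @param summaries List of [ice_set_summary()] objects.
#' @param labels Optional character labels carried through.
#' @param calibration An `ice_calibration`.
#' @return A tibble with label, combined_ics, p_ice, flag_ice, os_max,
#'   p_obs, flag_obs.
#' @export
evaluate_detection <- function(summaries, labels = NULL, calibration) {
  stopifnot(inherits(calibration, "ice_calibration"))
  ics <- vapply(summaries, function(x)
    .set_ics(x$stage1, calibration$w_ifs, calibration$w_ds,
             calibration$b_ice, calibration$b_protein)$combined, 0)
  os <- vapply(summaries, function(x) x$os_max %||% NA_real_, 0)
  p_ice <- p_upper(ics, calibration$gev_ics)
  p_obs <- p_upper(os, calibration$gev_os)
  tibble::tibble(
    label = labels %||% rep(NA_character_, length(summaries)),
    combined_ics = ics, p_ice = p_ice,
    flag_ice = p_ice <= calibration$p_ice_threshold,
    os_max = os, p_obs = p_obs,
    flag_obs = p_obs <= calibration$p_obs_threshold
  )
}
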