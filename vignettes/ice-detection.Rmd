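---
title: "Detecting and classifying ice contamination in structure-factor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying ice contamination in structure-factor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceringr)
```

## The problem

Ice that forms during cryocooling — in a protein crystal's internal
solvent, in residual surface solvent, or as frost — produces powder
diffraction rings at fixed resolutions. During integration, the background
under each protein Bragg peak is estimated from neighbouring pixels. A
narrow ice ring violates the locally-flat background assumption in two
ways: directly under a peak it is weaker in the neighbouring pixels, so the
background is underestimated and the integrated intensity inflated; next to
a peak it is stronger in the neighbours, so the background is overestimated
and the intensity depleted. Both artifacts are confined to narrow
inverse-resolution shells at known positions, which makes them detectable
from deposited structure factors alone.

`iceringr` turns that observation into a calibrated hypothesis test with an
interpretable p-value, and classifies detected ice as hexagonal (frost-like)
or stacking-disordered (solvent-derived).

## Ring geometry from the lattice

Ring positions, multiplicities and intensities are generated from the unit
cells rather than hard-coded. For hexagonal ice Ih the oxygens form a
wurtzite arrangement — four per cell at ±(1/3, 2/3, z) and
±(2/3, 1/3, 1/2 + z) — and for cubic ice Ic a diamond arrangement (eight
per cell). Structure factors use the oxygen Cromer–Mann form factor only:
hydrogen contributes about an eighth of the scattering and changes no
extinction. Reflections whose |F|² falls below 10⁻⁶ of the strongest ring
are systematic absences. We use the ideal tetrahedral oxygen height
z = 1/16, which makes the near-axial (004) and (104) reflections exact
extinctions; the experimentally refined z ≈ 0.0629 leaves them at ~10⁻⁴ of
the strongest ring — far below anything observable, but an awkward special
case for a threshold meant to separate exact zeros from small values.

With the default cells (hexagonal a = 4.4975 Å, c = 7.3224 Å; cubic
a = 6.358 Å ≈ a√2) this yields eleven rings between 4 and 1.5 Å, of which
exactly three — (002), (110), (112) — coincide with cubic-ice rings within
0.02 Å. These *common* rings are the only ones not broadened away by
stacking disorder, so stage-1 detection uses them alone. One honest wrinkle:
the diamond lattice also allows cubic (400) at 1.59 Å, which has no
hexagonal counterpart; it is kept in the cubic table with category `other`
and plays no role in detection.

Each ring carries two windows in inverse resolution: a ±0.003 1/Å *search*
window in which score maxima are taken, inside a ±0.010 1/Å *interpolation*
window excised from the background-trend estimate. The biased shells in
real data are about 0.005 1/Å wide, so the search window sits inside the
biased region while the interpolation window clears it. Both half-widths
are arguments.

## The score tracks

Reflections are binned in inverse resolution s = 1/d. Coarse bins of width
0.01 1/Å provide the smooth trends; bins whose centres fall in any
interpolation window are discarded and the gap bridged by linear
interpolation; the result is resampled on the fine 0.0025 1/Å grid. The
expected normalized mean f (mean over sd) is additionally smoothed with a
Gaussian of sd 0.01 1/Å, as is the expected count N̄; the expected
below-mean fraction D̄ is interpolated without smoothing. The fine bin width
is a compromise: small enough to resolve the ~0.005 1/Å biased shells,
large enough (~100 reflections) for stable bin statistics.

Per fine bin, three scores:

* **IFS = √N (⟨I⟩/σ̂ − f)** — positive when the normalized mean intensity
  is inflated. σ̂ is the interpolated *trend* standard deviation, not the
  bin's own: with ~100 reflections the own-sd estimate is noisy and biased
  low, which would both shift the null IFS mean upward (~+0.3) and dampen
  genuine ring bias, since bias inflates the local sd together with the
  mean. The √N scaling gives the track unit variance under the null
  (delta-method variance of mean/sd for exponential intensities is 1/N).
  Undefined for N < 3.
* **DS = (D̄ − D)/σ_off** — positive when below-mean intensities are
  depleted. D is the fraction of intensities strictly below the
  interpolated expected mean (ties count as not-below; using the bin's own
  mean would mask the bias being tested). σ_off is the standard deviation
  of D̄ − D over off-window bins, so the null track has unit sd by
  construction; fewer than 20 off-window bins, or zero spread (degenerate
  intensity distributions), are errors.
* **OS = (N̄ − N)/√N̄** — positive when reflections are missing. N̄ comes
  from the fine counts with ring regions excised, bridged and smoothed, so
  genuinely excluded shells stand out against their neighbours.

All three tracks are invariant under a global intensity rescale and under
record order, which the tests assert directly.

## From tracks to a decision

At each common ring the windowed maxima condense into an Ice Contamination
Score, ICS = (ω_IFS·max IFS + ω_DS·max DS)/(ω_IFS + ω_DS). The score
weights are Glass effect sizes — the separation of per-set maximum IFS (and
DS) between icy and clean training sets, in units of the clean sd — so the
more discriminating score earns more weight. Per-ring scores combine into
⟨ICS⟩ with weights ω_hkl = m F² exp[(B_protein − B_ice)/(2d²)]: the
Wilson-statistics intensity ratio of ice (B ≈ 1.5 Å²) to protein
(B ≈ 35 Å², a typical refined average) diffraction. Protein intensity
falls off much faster with resolution, so higher-resolution rings are more
detectable and weigh more.

A maximum over a handful of bins is approximately generalized extreme value
distributed, so the null for ⟨ICS⟩ is a GEV fitted by maximum likelihood to
the clean training subset (Gumbel moments as start; a Gumbel-only fallback
if the three-parameter fit fails). p_ice is the upper-tail probability — we
use the survival function so that small p means ice, consistent with
thresholds of the form p < 0.006. The same construction on the maximum of
the three ring-region mean OS values gives p_obs, which catches data sets
whose ice shells were *excluded* rather than biased. We read the summary
"⟨OS⟩" as the maximum of the three region means: exclusion at even a
single ring should drive the statistic.

Decision thresholds are the largest p with empirical training
false-discovery rate at or below 5% (p_ice) and 0.5% (p_obs). The
empirical FDR is a step function jumping at observed p values, so the
implementation takes the midpoint between the largest passing candidate and
the next one — same training flags, a little headroom for new data. With
unlabelled training the defaults 0.006 and 0.00005 apply.

Admission rules come first: fewer than 5000 reflections, or no data at the
lowest detection ring (3.661 Å), and the verdict is `insufficient_data` —
the metrics are noise-dominated there.

Sets flagged for ice are re-scored at the hexagonal-only (101), (102),
(103) rings, which stacking disorder strongly suppresses. Detection at any
one of them — per-ring ICS above that ring's null quantile at the level
matching the p_ice threshold (99.4th percentile at the default 0.006) —
classifies the ice as `hexagonal`; none, as `stacking_disordered`. The
per-ring criterion follows the "detected at any one of these locations"
reading; the null quantiles are empirical, taken from the clean calibration
sets.

## The synthetic ground truth

Every statistical stage is calibrated and tested against simulation:

* **Reflection sets.** Miller indices are subsampled from a mildly
  triclinic cell (irrational axis ratios, so no accidental d-degeneracies)
  sized to hold the requested count — resolution is then always recomputed
  from cell and indices, and the s²-density of reciprocal space comes for
  free. Intensities are acentric Wilson draws, I ~ Exp(Σ(s)) with
  Σ(s) = k·exp(−B_protein s²/2), B_protein = 35 Å²; reported sigmas follow
  a fractional (5%) plus additive (3% of the local mean) model and
  zero-mean Gaussian noise of that width is added, so weak intensities can
  be negative as in real background-subtracted data. Centric reflections
  are not modelled: the scores are bin-normalized, so the refinement would
  not change the calibration.
* **Bias injection** adds b(s) = A·Σ(s)·[L(s − s₀) − φ(1 − L(s − s₀))]
  inside a ring's interpolation window: a unit-peak Lorentzian core
  (half-width 0.001 1/Å) with negative flanks of depth φ = 0.2·A — the two
  background-subtraction failure modes. The amplitude is in units of the
  local Wilson mean, so the injected data keep the scale-invariance the
  scores assume. The true core/flank shape in real data depends on the
  integration software; φ is a free parameter, not a fitted one.
* **Exclusions** remove a fraction of records in ring windows uniformly at
  random; **frames** are Poisson backgrounds plus radial-Lorentzian rings
  (optionally modulated by a three-component von Mises mixture for
  lumpiness) and single-pixel hot spots at stated multiples of background.

The default training mix for calibration — 80% clean, 20% biased with
amplitude log-uniform in [0.5, 4] — spans barely-visible to gross
contamination. What the simulations do *not* emulate: anisotropic
diffraction, resolution-dependent completeness structure, twinning,
outlier-rejected integration, or real detector point-spread. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the stated model, not that real-PDB error rates will match exactly.

## Powder patterns, mixtures and crystallite sizes

1D patterns are sums over rings of m·F²·Lp(θ)·exp(−B_ice s²/2) times a
unit-area Lorentzian or Gaussian profile, with the width given as an
integral breadth in 2θ degrees and converted through ds = cosθ/λ·d2θ.
Unit-area profiles make integrated intensities width-invariant, which the
tests check to 1%.

The hexagonal/cubic mixture fit models an observed pattern as a linear
combination of the two pure-phase patterns sharing one broadening width and
one isotropic cell-scale factor, plus a tenth-order polynomial background
fitted to the data-minus-model difference. The component scales and
background coefficients enter linearly, so they are profiled out exactly by
least squares (negative scales clamped to zero and refitted) inside a
two-parameter optimization over width and cell scale — equivalent to
alternating scale refinement with background polishing, in one pass. The
cubic fraction is the cubic share of integrated ring intensity. A genuinely
stacking-disordered pattern, which is neither phase nor a mixture, will fit
with broad widths and an intermediate fraction — a documented limitation,
since layer-stacking recursion is out of scope.

Crystallite sizes come from the Scherrer relation δ = Kλ/(β cosθ) with
K = 1, applied to the integral breadth (area/height, linear background from
the window edges) of the (002) ring — the lowest-angle ring free of
stacking-disorder broadening, where strain and fault contributions are
smallest; other rings trigger a warning. The instrumental contribution
(Gaussian, integral breadth 0.037°) is removed by inverting the exact
Voigt integral-breadth relation β_V = β_G·exp(−k²)/erfc(k) with
k = β_L/(√π β_G), by bracketed root finding to 10⁻¹⁰ relative; the
uncorrected size is also reported as a lower bound. Recovery on synthetic
rings is within 10% across 200–2000 Å.

## Frames

Pixel ↔ (s, azimuth) mapping treats the detector as a plane at the sample
distance whose basis is rotated by two small tilts; the inverse mapping is
an exact ray–plane intersection, and round-trips are sub-pixel. Azimuthal
averaging is a binned mean of unmasked pixels. Ice spots are pixels
exceeding five times the local background — the median of their 21×21
neighbourhood — optionally restricted to ±0.02 1/Å annuli around the
expected rings. The annulus width is our choice (it is not constrained by
anything physical beyond covering ring-position jitter) and is an
argument. Beam-centre
and tilt refinement minimizes the summed integral ring breadths
(sharp rings = correct geometry) with a robust breadth measure: bins with
fewer than five pixels are ignored and the peak height is a three-bin
running mean, so a single noisy bin cannot fake a sharp ring. The two
tilts are nearly degenerate with a centre shift on a flat detector;
`refine_tilt = FALSE` is available when tilts are known small.

## Numerical choices and scales

Half-open binning [lo, hi) anchored at the data's minimum s; Gaussian
smoothing kernels truncated at 4σ and renormalized at edges and across
gaps; windows clipped to the data range with an `edge-window` flag when a
trend must be extended; GEV fits by Nelder–Mead on the negative
log-likelihood. Problem sizes in the test suite are chosen so the whole
suite runs in a couple of minutes on one core: calibrations use 120–150
sets of 8000–10 000 reflections; the detection-rate checks use the full
500 × 20 000 design; the spot-recovery frames are 1100² pixels at 0.1 mm
pitch so that one pixel subtends well under the 0.01 Å match tolerance at
the lowest-resolution ring.

## Known limitations

* The detector is calibrated against the synthetic model above; real-data
  error rates depend on how far real backgrounds deviate from it.
* Amplitude-only depositions are squared into intensities (with first-order
  error propagation) and flagged; the scores were designed for intensities.
* Stacking-disorder physics (layer-stacking recursion, stacking-probability
  estimation) is out of scope; the mixture fit brackets such patterns
  rather than modelling them.
* MTZ input requires the external `gemmi` Python module; the text and mmCIF
  dialects have no external dependencies.
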