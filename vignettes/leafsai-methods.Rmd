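---
title: "Adaptive spectral absorption indices for leaf water status: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive spectral absorption indices for leaf water status: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafsai)
```

## The estimation problem

Two variables summarise a leaf's water status. Equivalent water thickness,

$$\mathrm{EWT} = \frac{FW - DW}{A} \quad [\mathrm{g\,cm^{-2}}],$$

is the mass of water per unit leaf area, and fuel moisture content,

$$\mathrm{FMC} = \frac{FW - DW}{FW},$$

is water as a fraction of fresh mass (conventionally printed as a
percentage; `leafsai` keeps it as a fraction internally and formats as
percent only at output boundaries, which also resolves the common
ambiguity of summary tables that mix the two conventions). Here $FW$ and
$DW$ are fresh and dry mass (g) and $A$ is single-sided leaf area
(cm^2^).

Leaf reflectance between 900 and 2000 nm carries strong water
absorption features near 970, 1200, 1450 and 1950 nm, and a dry-matter
(lignin/cellulose) feature near 1660 nm that becomes more visible as
water decreases. Classical hyperspectral water indices (WI, SRWI, NDWI,
MSI, NDII, GVMI, RDI, DWI and the three-band RATIO indices) read fixed,
predefined wavelengths for every leaf. But the exact position of an
absorption peak varies from leaf to leaf and species to species —
water content itself shifts the 970/1200-nm features toward shorter
wavelengths as leaves get wetter — so fixed bands read slightly
different parts of the feature on different leaves.

## The spectral absorption index

The adaptive alternative implemented here describes one absorption
feature by three per-leaf wavelengths: the two shoulders $\lambda_1 <
\lambda_2$ (local reflectance maxima flanking the dip) and the peak
$\lambda_m$ (the reflectance minimum between them). The straight line
between the shoulders is the non-absorption baseline. With the symmetry
parameter

$$d = \frac{\lambda_2 - \lambda_m}{\lambda_2 - \lambda_1} \in (0, 1),$$

the baseline evaluated at the peak wavelength is exactly the
$d$-weighted mix of the shoulder reflectances, and the spectral
absorption index is the relative absorption depth

$$\mathrm{SAI} = \frac{d\,\rho_1 + (1-d)\,\rho_2}{\rho_m},$$

where $\rho_1, \rho_2, \rho_m$ are reflectances at the three located
wavelengths. SAI equals 1 when the peak sits on the baseline (no
absorption) and grows with dip depth; because it is a ratio of
reflectances of one spectrum it is exactly invariant to any positive
rescaling of that spectrum. The weighting identity — $d\rho_1 +
(1-d)\rho_2$ equals the two-point shoulder line at $\lambda_m$ — is
asserted to machine precision in the test suite; it is the reason the
index needs no explicit line fit.

Three windows are configured by default:

| index | window (nm) | left shoulder search | right shoulder search | driven by |
|---|---|---|---|---|
| SAI_970 | 915–1085 | 915–940 | 1060–1085 | water |
| SAI_1200 | 1085–1265 | 1085–1110 | 1240–1265 | water |
| SAI_1660 | 1630–1690 | 1630–1645 | 1675–1690 | dry matter |

The windows follow the standard placement of these leaf features; the
shoulder search sub-ranges take roughly the outer quarter of each
window on each side, because the shoulders of these features sit at the
window edges. All ranges are configurable (`absorption_window()`, YAML
config).

### Locating the extrema, and why values are read from the smoothed spectrum

Shoulders are argmax over their search ranges and the peak is argmin
strictly between the shoulders, ties resolving to the smallest
wavelength (deterministic and order-independent). Location on a noisy
spectrum is noise-sensitive, so by default a local quadratic
(Savitzky–Golay, 15-nm window) smoothed copy is used for the search.

The reflectance *values* at the located wavelengths are also read from
that smoothed copy. This is a deliberate design choice: the SG value at
a point is the local quadratic estimate of the true reflectance there,
and an index built from three single raw channels would carry the full
per-channel measurement noise while every fixed-band competitor
averages 20–40 channels. On simulated data at realistic noise
(sd 0.002 reflectance units) the smoothed read roughly halves the
index's cross-validated error and is what lets the adaptive index's
location advantage show through; the bias of a quadratic-preserving
filter at a local extremum is negligible at these feature widths.
`smooth = FALSE` disables smoothing entirely (raw locations, raw
values) for sensitivity analysis.

### Degenerate windows

A window with no interior dip cannot support the construction. Two
conventions apply:

* an exactly constant window is the no-absorption case: ties resolve to
  the search-range edges, the feature stays valid, and SAI evaluates to
  exactly 1;
* otherwise, if the interior minimum lands immediately adjacent to a
  shoulder ($\lambda_1 + 1$ or $\lambda_2 - 1$), there is no true dip —
  the window is a monotone slope — and the feature is marked invalid.
  Downstream regression drops such samples for that index and reports
  the count, rather than fabricating a depth.

## Classical indices

The ten comparison indices are computed exactly as conventionally
defined (see `?compute_classic_indices`), on a 1-nm grid with band
means taken as unweighted arithmetic means over integer wavelengths,
range-inclusive. Two details worth noting:

* the DWI baseline is the two-point line through $(850, \rho_{850})$
  and $(1080, \rho_{1080})$ evaluated at 970 and 1200 nm;
* the RDI minimum is taken over 1120–1150 nm (the formula's subscript;
  published statements of this range are not fully consistent, and the
  range is config-overridable in spirit via the source).

Algebraically, WI, SRWI, MSI, the RATIOs, NDWI, NDII *and RDI* are
invariant to rescaling the spectrum (pure ratios), while GVMI (additive
constants) and DWI (absolute depths) are not; the tests assert each
case.

## Cross-validated evaluation

Indices are related to EWT or FMC by three functional forms — linear
$y = b_1 x + b_0$, quadratic $y = b_2 x^2 + b_1 x + b_0$ (both OLS) and
exponential $y = a e^{bx}$ (Levenberg–Marquardt, log-linear start) —
and judged by 10-fold cross-validation. Samples are randomly permuted
and dealt round-robin, so fold sizes differ by at most one (292 samples
give eight folds of 29 and two of 30). Every sample is predicted
exactly once out-of-fold; pooled predictions give

* $R^2_{cv}$: by default the squared Pearson correlation between
  out-of-fold predictions and observations. The alternative
  $1 - SSE/SST$ definition is available (`r2_variant = "sse"`); the two
  differ when the prediction variance is miscalibrated, and the
  correlation form is the common reading of "cross-validated
  coefficient of determination".
* $rRMSE_{cv}$: the out-of-fold RMSE divided by the mean of the
  observed target, reported as a percentage.

Fold assignment is seeded (default 20190515) and unstratified; a
species-stratified option would be a small extension but plain k-fold
is the default. The association p-value used for the "n.s." flag in
ranking reports is the F-test of the best-form full-data regression
against the intercept-only model at $\alpha = 0.05$.

One artifact is worth knowing about: `similarity_analysis()` correlates
two indices' out-of-fold *prediction vectors*. For two informative
indices this measures whether they carry the same information (values
near 1). For two uninformative indices the predictions collapse toward
the fold training means, which both vectors share, so the null
similarity is bounded near 0.3–0.4 rather than 0. Interpret similarity
only for indices that individually predict the target.

Per-species fits (`group_by_species()`) are full-data fits within each
species (minimum 5 samples, smaller species skipped with a warning) and
report the spread of coefficients across species — a small spread means
the index–target relation transfers across species.

## The synthetic-data generator

Every numerical claim in the package is exercised on synthetic leaves
with known ground truth, generated as

$$\rho(\lambda) = C(\lambda)\Bigl(1 - \sum_k D_k
  e^{-(\lambda - \mu_k)^2 / 2\sigma_k^2}\Bigr) + \varepsilon(\lambda),$$

clipped to $(0.001, 1)$, with:

* **continuum** $C$: a red-edge sigmoid rising 0.05 → 0.48 across
  700–760 nm, gently declining beyond 1300 nm;
* **water dips** at nominal 970/1200/1450/1950 nm with depths
  proportional to EWT — at EWT = 0.010 g cm^-2^ they are
  0.06/0.12/0.55/0.75, capped at 0.95. Widths (20/25/45/60 nm) are
  chosen so the 970- and 1200-nm features are *contained* within their
  shoulder windows (tails below ~4% at the shoulders): the construction
  requires the window-edge shoulders to be near-absorption-free local
  maxima, and a feature that leaks past its shoulders would contradict
  the physics the index assumes;
* **dry-matter dip** at 1660 nm with depth $0.08\,(1 - \mathrm{FMC})/0.40$,
  width 12 nm, strengthening as FMC falls;
* **heterogeneity**: every centre gets per-leaf Normal(0, 5 nm) jitter,
  and the water-band centres additionally shift deterministically toward
  shorter wavelengths as EWT rises (8 nm per 0.010 g cm^-2^ above the
  0.010 midpoint), reproducing the blue-shift of the 970/1200-nm
  features reported for wetter leaves. This leaf-to-leaf variation in
  feature position is exactly what the adaptive indices are designed
  for;
* **noise**: i.i.d. Normal(0, 0.002) reflectance units, a realistic
  post-averaging noise level for contact leaf spectroscopy.

The default study design mirrors a three-species pooled campaign: 46 +
66 + 180 = 292 leaves with per-species EWT ranges spanning 0.006–0.016
g cm^-2^ and FMC ranges spanning 45.2–82.7%. Leaf area is drawn
uniformly on 10–40 cm^2^ and the gravimetric measurements are
back-solved ($W = \mathrm{EWT}\cdot A$, $FW = W/\mathrm{FMC}$,
$DW = FW - W$) so the EWT/FMC formulas recover the drawn truths to
machine precision. Everything is deterministic given the seed.

### What the generator does not emulate

* No radiative-transfer realism (no PROSPECT-style leaf structure
  parameter); the continuum is shared by all leaves, which if anything
  *flatters* the fixed-band indices relative to real data.
* EWT and FMC are drawn independently within species, whereas in real
  leaves they correlate; synthetic FMC skill of the water-band indices
  (e.g. SAI_970–FMC) is therefore near zero by construction and should
  not be read as a statement about real leaves.
* The 1450/1950-nm bands are narrow Gaussians, so reflectance at
  1600 nm barely senses water and the SWIR indices (MSI, NDII, GVMI)
  underperform the skill they show on real spectra. This affects only
  the realism of the comparison table, not any property the tests
  assert.
* No visible-region pigment features, canopy/BRDF effects, or
  instrument artifacts beyond additive noise.

Passing tests on this generator therefore demonstrate the mechanics and
the heterogeneity-robustness of the indices — not field-level accuracy
on any particular species.

## Numerical choices and degenerate inputs

* Wavelengths are integer nanometres; all ranges are inclusive on both
  ends. Spectra are linearly resampled to the 1-nm grid; interior gaps
  wider than 5 nm are an error rather than silently bridged.
* Reflectance is expected in [0, 1]: values outside [−0.05, 1.2] are
  rejected, values outside [0, 1] within those bounds kept with a
  warning, and percent-scaled input (max > 1.5) auto-divided by 100
  with a warning.
* Replicate readings of one leaf (duplicate rows in the long CSV
  layout) are averaged pointwise, mirroring the usual
  three-readings-per-leaf protocol.
* Argmax/argmin ties resolve to the smallest wavelength.
* The exponential fit requires strictly positive responses (true for
  EWT and FMC) and errors, naming the form, if the optimiser fails.
* Coefficients are printed to 3 decimals in report equations; machine
  output keeps full precision.

## Problem sizes used by the test suite

Module tests run on small spectra sets (tens of leaves) built in code;
the end-to-end property tests use one shared dataset at the default
study design (292 leaves, jitter 5 nm, noise 0.002). On one CPU the
full suite runs in well under a minute, and `scripts/acceptance.R`
(which regenerates the study, recomputes all indices and
cross-validates the headline pairs) in a few seconds.
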