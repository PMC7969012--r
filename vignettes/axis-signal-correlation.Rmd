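---
title: "Quantifying signal co-distribution along meiotic chromosome axes"
author: "axiscor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signal co-distribution along meiotic chromosome axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axiscor)
```

## The question the package answers

During meiotic prophase, programmed DNA double-strand breaks (DSBs) are
made by SPO11 on chromosome axes, where auxiliary proteins such as IHO1
form a discontinuous axial "platform" and recombinases (DMC1, RAD51)
mark resected DSB ends as cytological foci. A central mechanistic
question is whether DSBs feed back on the machinery that made them — for
example by locally depleting the IHO1 platform in their vicinity. On
immunofluorescence spreads this hypothesis makes a spatial prediction:
along an unsynapsed axis, focus-channel peaks should coincide with
platform-channel valleys.

`axiscor` turns that prediction into a statistic. It extracts
width-averaged intensity profiles along manually traced axis fragments,
z-scales each fragment, and estimates averaged auto- and
cross-correlation curves over axial distance with per-lag significance
tests. The axial coordinate is in pixels; with the supported imaging
setup one pixel corresponds to 65 nm of axis.

## The statistic

For each traced fragment $f$ of length $L$, each channel's profile
$I_0, \dots, I_{L-1}$ (already background-subtracted) is centered and
scaled:

$$ s_i = \frac{I_i - \bar I}{\hat\sigma_I}, $$

with $\hat\sigma_I$ the sample standard deviation (divisor $L - 1$).
The scaled primary (platform) series is $s$, the scaled partner (focus)
series is $r$. For an unsigned axial lag $x = |i - j|$ the fragment's
mean products are

$$ \langle s_i s_j \rangle_f \quad\text{and}\quad
   \langle s_i r_j \rangle_f, \qquad |i - j| = x, $$

and the reported curves average these per-fragment means with equal
weight over all fragments of a condition:

$$ c(x) = \frac{1}{\#\text{frag}} \sum_f \langle s_i s_j \rangle_f,
   \qquad
   g(x) = \frac{1}{\#\text{frag}} \sum_f \langle s_i r_j \rangle_f. $$

Because the lag is unsigned, cross products at $x > 0$ include both
orientations ($s_i r_{i+x}$ and $s_{i+x} r_i$); auto products use a
single orientation so identical pairs are not counted twice. Fragments
shorter than $x + 1$ simply contribute nothing at lag $x$. A negative
$g(0)$ means focus peaks sit preferentially in platform valleys at the
same axial position; the lag at which $g$ crosses back to positive
values reads off the spatial extent of the local anticorrelation.

Two details follow from the sample-sd convention and are asserted in
the test suite rather than hidden:

* $c(0)$ equals the cohort mean of $(L_f - 1)/L_f$ exactly (close to,
  but deliberately not forced to, 1);
* fragments with a zero-variance channel cannot be scaled and are
  excluded with a counted warning before curve estimation.

### Estimators

`correlationCurve()` exposes two estimators. The default,
`fragment_mean`, averages per-fragment expectations with equal weight —
this is the definition displayed above and treats the fragment as the
unit of replication regardless of its length. The `pooled` alternative
averages all products of a lag directly, which weights fragments by
their number of admissible pairs; it matches what classical correlogram
estimators (`stats::acf`/`ccf`) do per series and is retained because
the two conventions differ when fragment lengths vary. Which estimator
was used is recorded in every curve object and output sidecar.

### Per-lag significance

At each lag a two-sided one-sample *t*-test evaluates the null
hypothesis that the scaled signals are uncorrelated, $c(x), g(x) = 0$.
The sample unit is a choice with real consequences:

* `sampleUnit = "product"` (default) treats each individual product
  $s_i s_j$ as a sample. With tens of thousands of products this
  reproduces the very small p-values typical of this assay, but
  products within a fragment are not independent — smooth signals make
  nearby products correlated — so these p-values are optimistic. The
  caveat is documented here on purpose rather than silently "fixed".
* `sampleUnit = "fragment_mean"` treats each fragment's mean product as
  one sample. Fragments are independent units (different axes,
  different cells), so this test is calibrated, and it is what the
  package's own null-calibration checks use: on no-depletion synthetic
  cohorts the lag-0 test at $\alpha = 0.05$ rejects in no more than
  10% of seeds.

`compareConditions()` contrasts two curves lag by lag with a Welch
two-sample *t*-test on the chosen sample units, with Bonferroni and
Benjamini–Hochberg columns across the compared lags.

## Profile extraction

Traces are polylines in (row, col) pixel coordinates, 0-based, pixel
centers at integer coordinates. `sampleProfile()` resamples the
polyline at unit arc-length steps (output indexed from position 0,
`floor(arc length) + 1` values) and, at each step, averages `widthPx`
bilinear samples taken at unit spacing along the local normal. That
approximates how ImageJ's wide-line `getProfile` averages over the line
width — a 5-pixel width covers the whole axis thickness in the intended
use — without promising bit-identical agreement with ImageJ internals
(which are not fully specified for freehand wide lines; pre-extracted
tables can bypass this stage entirely via `importExternalTable()`).
A trace that leaves the image after width expansion is an error, never
silently clipped.

Background is measured per cell as the mean intensity over the union of
2–3 nuclear regions away from axes (overlapping regions counted once;
union is the conservative choice since the convention is unstated in
typical protocols), and subtracted per channel. Negative values after
subtraction are kept: scaling removes the fragment mean anyway, and
clipping would bias it.

## The synthetic generator

Real spreads come with manual tracing and no public raw data, so the
package ships a generator that emulates exactly the structure the
statistic assumes, making the whole pipeline testable end to end:

* **platform channel** — `smooth(max(0, base + noise))`: Gaussian
  texture (sd `platformNoiseSd`) on a base level, clipped at zero
  (intensities are physical), then Gaussian-smoothed
  (`platformSmoothSigmaPx`). Clipping a strongly fluctuating texture
  produces the patchy, discontinuous platform appearance.
* **focus channel** — Gaussian peaks of amplitude `focusAmp` and width
  `focusSigmaPx` placed by a Poisson process (`focusRatePerPx`).
* **local depletion** — each focus multiplies the platform by
  $1 - d\,e^{-(i-p)^2 / 2\sigma_d^2}$ with depth $d \in [0, 1]$
  (`depletionDepth`) and width $\sigma_d$ (`depletionSigmaPx`).
  Depletion is multiplicative, not subtractive, so the platform stays
  non-negative.
* **coupling** — optionally, focus placement is biased toward platform
  peaks (positive `coupling`) or valleys (negative) by rejection
  sampling with an exponential acceptance weight on the normalized
  pre-depletion platform; the rejection loop is capped at 1000 tries
  per focus and falls back to uniform with a warning.
* **noise** — i.i.d. Gaussian noise (`noiseSd`) on both channels, in
  arbitrary units as in the assay.

Defaults (fragment lengths 30–120 px, base 60, texture sd 100,
smoothing 3 px, focus rate 0.02/px, amplitude 120, focus width 3 px,
depletion width 6 px, noise sd 40, 65 nm/px) were chosen once so that
the depleted regime lands in the empirically observed range of the
statistic — $g(0)$ near $-0.15$ to $-0.2$ with a positive crossing
between 5 and 15 px — while the no-depletion regime is null. Focus
rate 0.02/px corresponds to roughly 0.3 foci per µm of axis, a
realistic order for recombinase foci on zygotene axes. No claim is made
of estimating biological parameters from the generator; it is a
validation instrument.

`genotypePresets()` packages the three qualitative regimes the assay
distinguishes: `wt_like` (depletion depth 0.7), `atr_null_like` (no
depletion — DSB foci form but do not locally deplete the platform, as
when ATR signaling is absent), `atr_atm_null_like` (no depletion,
coupling +0.5 — foci preferentially on platform-rich axis produce a
weak positive $g(0)$), and `irradiation_1h_like` (no depletion,
uniform placement — freshly induced exogenous DSBs that have not yet
triggered depletion).

What the generator deliberately does **not** emulate: 2-D/3-D nuclear
geometry and axis curvature (fragments are 1-D; rendering lays them as
straight lines), chromatic shift between channels, focus amplitude
variation, stage-dependent global platform loss, or any of the
kinase-mediated feedback mechanisms themselves. Passing the validation
suite therefore shows the estimator and tests behave correctly on
signals with the assumed structure — it cannot certify conclusions
about real images beyond that structure.

## Validation design and problem sizes

The test suite validates against independent oracles: a brute-force
all-pairs double loop for curve values (small fragments, tolerance
1e-12), `stats::acf` with the pair-count correction for the pooled
estimator, the incomplete-beta identity for *t*-tail probabilities,
exhaustive permutation enumeration for Mann–Whitney, and the closed
form for the G statistic. Monte-Carlo properties use cohorts of 500
fragments over 20 fixed seeds — large enough that the per-cohort
standard error of $g(0)$ (about 0.013) cleanly separates the regimes —
including: null calibration (≤ 10% lag-0 rejections without
depletion), effect detection in the depleted and coupled regimes, rank
recovery of the depletion depth (Spearman 1 across
$d \in \{0, 0.25, 0.5, 0.75, 1\}$), growth of the positive crossing
lag with depletion width ($\sigma_d \in \{3, 6, 9\}$ px), and an
image round trip (render with a 1 px PSF, re-extract, per-fragment
correlation with ground truth; the round-trip fixture is noiseless
because it validates sampling geometry, not denoising).

## Numerical choices and degenerate inputs

* Bilinear interpolation at fractional coordinates; width-1 sampling on
  a grid-aligned trace reduces to exact pixel lookup.
* Gaussian smoothing inside the generator renormalizes the kernel at
  the edges (a constant stays constant); the rendering PSF does not
  (light leaving the field of view is lost, as with a real PSF).
* Sample sd uses divisor $L - 1$ throughout; the resulting exact
  $c(0) = (L-1)/L$ invariant is asserted, not patched.
* Zero-variance t-test samples report $p = 0$ (nonzero mean) or
  $p = 1$ (zero mean) with a degenerate flag; lags with fewer than two
  samples report NA.
* Lags at which no fragment contributes are an error naming the lag,
  not a silently missing row.
* Profile tables with position gaps are split at the gaps on import,
  with counts logged; missing values inside a fragment are not
  supported.
* Pipeline outputs are written with fixed formatting so identical
  configs and seeds give byte-identical tables; every output is listed
  with an md5 digest in `manifest.json`.

## Limitations

* The ImageJ wide-line average is approximated (perpendicular unit-
  spaced bilinear samples); sub-pixel differences to ImageJ's freehand
  implementation cannot be arbitrated without its exact internals.
* Product-unit p-values ignore within-fragment dependence (see above);
  use fragment means when calibration matters.
* The equal-weight fragment average treats a 30 px fragment and a
  120 px fragment as one unit each; the pooled estimator covers the
  length-weighted alternative.
* `focusDensity()`, `intensityRatio()`, `likelihoodRatioTest()` (the
  2×2 G-test of independence, df = 1 — the standard reading of a
  likelihood-ratio comparison of two proportions) and `mannWhitney()`
  operate on counts and region means that are produced by manual
  scoring upstream; the package validates the statistics, not the
  scoring.
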