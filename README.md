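# axiscor

Correlation analysis of immunofluorescence signals along meiotic
chromosome axes.

## What it is for

On nuclear spreads of meiotic prophase cells, DSB-machinery proteins
such as IHO1 form a patchy "platform" along unsynapsed chromosome
axes, while recombinases (DMC1, RAD51) mark DNA double-strand breaks
as discrete foci. Whether DSBs locally deplete the platform around
themselves is a spatial question: do focus peaks coincide with
platform valleys along the axis? `axiscor` answers it quantitatively
for researchers analysing such spreads. It

* extracts width-averaged, background-subtracted intensity profiles
  from multi-channel TIFFs along manually traced axis fragments
  (ImageJ `.roi`/`RoiSet.zip` or plain-TSV traces),
* z-scales each fragment and estimates averaged auto- and
  cross-correlation curves over axial distance with per-lag
  significance tests,
* ships a synthetic fragment generator (platform texture, Poisson
  focus peaks, local depletion, optional placement coupling) so the
  entire pipeline is validated end to end without any raw images,
* provides the accompanying cohort statistics: focus densities per µm,
  background-corrected intensity ratios, 2×2 likelihood-ratio (G)
  tests of proportions, and exact/midrank Mann–Whitney U tests.

## The statistic

Each traced fragment's channel profile is centered and scaled,
`s_i = (I_i - mean) / sd` (sample sd, divisor L−1). With `s` the
platform series and `r` the focus series, per fragment *f* and
unsigned axial lag `x = |i − j|` (1 px = 65 nm of axis):

    c(x) = Σ_f <s_i s_j>_f / #fragments      (auto-correlation)
    g(x) = Σ_f <s_i r_j>_f / #fragments      (cross-correlation)

Per-lag two-sided one-sample t-tests evaluate the null that the scaled
signals are uncorrelated, `c(x), g(x) = 0`. A negative `g(0)` means
focus peaks sit in platform valleys; the lag at which `g` turns
positive measures the spatial extent of the local depletion. See the
vignette (`vignettes/axis-signal-correlation.Rmd`) for estimator and
sample-unit choices and their caveats.

## Worked example

```r
library(axiscor)

params <- getPreset("wt_like")      # depletion depth 0.7, no coupling
params@seed <- 20L
cohort <- generateCohort(params, nFragments = 300L)

scaled <- scaleCohort(cohort, "platform", "focus")
g <- correlationCurve(scaled, "cross", xMax = 20)
g
#> CorrelationCurve (cross, fragment_mean estimator, t-test unit: product)
#>   lags 0..20 px (65 nm/px), 300 fragments / 30 cells
#>   value at lag 0: -0.18041 (p = 2.63e-168)

head(as.data.frame(g), 4)
#>   lag_px distance_nm   value      sem n_products n_fragments    p_value
#> 1      0           0 -0.1804 0.006836      22311         300 2.629e-168
#> 2      1          65 -0.1771 0.004852      44022         300 1.087e-321
#> 3      2         130 -0.1781 0.004844      43422         300 8.605e-315
#> 4      3         195 -0.1601 0.004895      42822         300 4.071e-245

firstPositiveLag(g)
#> [1] 12
```

The strongly negative `g(0)` with a tiny p-value says that, at the
same axial position, focus peaks coincide with platform valleys — the
depletion signature built into the `wt_like` preset. The
anticorrelation fades with distance and crosses to a weak positive
correlation at lag 12 (≈ 0.78 µm here), reflecting the width of the
depleted zone around each focus. With the `atr_null_like` preset
(no depletion) the same analysis gives `g(0) ≈ 0` with p > 0.05.

Cohort statistics follow the same one-call pattern:

```r
mannWhitney(c(22, 25, 24, 26, 23), c(21, 24, 23, 22, 25))
#> $U 17  $p_value 0.398  $method "normal_approx"
likelihoodRatioTest(matrix(c(58, 44, 42, 56), 2))
#> $G 3.9345  $df 1  $p_value 0.0473
```

To analyse real measurements instead, feed `importExternalTable()` a
delimited table of background-subtracted per-position intensities with
a column map, or run the full pipeline over images + traces with
`runPipeline(runConfig(mode = "images", ...))`; every run writes curve
TSVs plus a `manifest.json` with digests, and identical seeds give
byte-identical outputs.

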