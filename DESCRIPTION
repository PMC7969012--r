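Package: axiscor
Title: Correlation Analysis of Immunofluorescence Signals Along Meiotic
    Chromosome Axes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the co-distribution of immunofluorescence signals
    along traced meiotic chromosome axes. Extracts width-averaged,
    background-subtracted intensity profiles from multi-channel images
    along polyline axis traces, z-scales each axis fragment, and computes
    fragment-averaged auto- and cross-correlation curves c(x) and g(x)
    over axial pixel lags with per-lag one-sample t-tests against the
    null of no spatial association. Includes a synthetic fragment
    generator (patchy axial platform signal, Gaussian focus peaks placed
    by a Poisson process, multiplicative local depletion of the platform
    around foci) for end-to-end validation, plus focus-density,
    intensity-ratio, likelihood-ratio (G) and Mann-Whitney U utilities
    for chromosome-spread cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-stats.R'
    'correlation.R'
    'dialects.R'
    'pipeline.R'
    'plots.R'
    'profile-extraction.R'
    'roi-io.R'
    'synthetic.R'
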