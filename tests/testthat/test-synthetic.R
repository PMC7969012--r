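test_that("generation is deterministic under a fixed seed", {
  p <- syntheticParams(seed = 101L)
  cohA <- generateCohort(p, nFragments = 20L)
  cohB <- generateCohort(p, nFragments = 20L)
  expect_identical(lapply(cohA, intensityMatrix),
                   lapply(cohB, intensityMatrix))
  expect_identical(attr(cohA, "groundTruth"), attr(cohB, "groundTruth"))
})

test_that("without depletion the platform is independent of the foci", {
  # platform texture is drawn before the focus process, so the same seed
  # with the focus process disabled must reproduce the identical platform
  pFoci <- syntheticParams(depletionDepth = 0, noiseSd = 0,
                           focusRatePerPx = 0.1)
  pNone <- syntheticParams(depletionDepth = 0, noiseSd = 0,
                           focusRatePerPx = 0)
  set.seed(31); fA <- generateFragment(pFoci, L = 80)
  set.seed(31); fB <- generateFragment(pNone, L = 80)
  expect_gt(length(fA@focusPositions), 0)
  expect_identical(fA@platformTrue, fB@platformTrue)
})

test_that("depletion is multiplicative and full depth zeroes the center", {
  # same seed, same rate: d = 1 and d = 0 runs share platform texture and
  # focus positions, so the depletion factor is recoverable exactly
  p1 <- syntheticParams(depletionDepth = 1, noiseSd = 0,
                        focusRatePerPx = 0.05, depletionSigmaPx = 4)
  p0 <- syntheticParams(depletionDepth = 0, noiseSd = 0,
                        focusRatePerPx = 0.05, depletionSigmaPx = 4)
  set.seed(32)
  repeat {
    st <- .Random.seed
    f1 <- generateFragment(p1, L = 60)
    if (length(f1@focusPositions) >= 1) break
  }
  assign(".Random.seed", st, envir = globalenv())
  f0 <- generateFragment(p0, L = 60)
  expect_identical(f1@focusPositions, f0@focusPositions)
  i <- 0:59
  fac <- rep(1, 60)
  for (pp in f1@focusPositions)
    fac <- fac * (1 - exp(-(i - pp)^2 / (2 * 4^2)))
  expect_equal(f1@platformTrue, f0@platformTrue * fac, tolerance = 1e-12)
  # at an exactly-hit center the platform is zero
  expect_equal(f1@platformTrue[round(f1@focusPositions[1]) + 1] /
                 max(f0@platformTrue), 0, tolerance = 0.05)
})

test_that("focus peaks integrate to amp * sigma * sqrt(2*pi)", {
  for (sigma in c(2, 3, 5)) {
    p <- syntheticParams(focusSigmaPx = sigma, focusAmp = 100,
                         depletionDepth = 0, noiseSd = 0,
                         focusRatePerPx = 0.005, lengthRange = c(200L, 200L))
    set.seed(33 + sigma)
    repeat {
      fr <- generateFragment(p, L = 200)
      k <- length(fr@focusPositions)
      # need foci away from the edges for the discrete integral to close
      if (k >= 1 && all(fr@focusPositions > 6 * sigma) &&
          all(fr@focusPositions < 200 - 6 * sigma)) break
    }
    expect_equal(sum(fr@focusTrue), k * 100 * sigma * sqrt(2 * pi),
                 tolerance = 0.02)
  }
})

test_that("positive coupling enriches foci on platform-rich positions", {
  p <- syntheticParams(depletionDepth = 0, coupling = 0.9, noiseSd = 0,
                       focusRatePerPx = 0.05)
  set.seed(34)
  above <- below <- 0
  for (i in 1:40) {
    fr <- generateFragment(p, L = 100)
    med <- median(fr@platformTrue)
    at <- fr@platformTrue[round(fr@focusPositions) + 1]
    above <- above + sum(at > med); below <- below + sum(at <= med)
  }
  expect_gt(above, 1.5 * below)
})

test_that("presets are stable identifiers with documented regimes", {
  pr <- genotypePresets()
  expect_true(all(c("wt_like", "atr_null_like", "atr_atm_null_like",
                    "irradiation_1h_like") %in% names(pr)))
  expect_equal(pr$wt_like@depletionDepth, 0.7)
  expect_equal(pr$atr_null_like@depletionDepth, 0)
  expect_equal(pr$atr_atm_null_like@coupling, 0.5)
  expect_error(getPreset("nonesuch"), "unknown preset")
})

test_that("params round-trip through list serialization (YAML-safe)", {
  for (nm in names(genotypePresets())) {
    p <- getPreset(nm)
    lst <- paramsToList(p)
    # through an actual YAML file, as a config would be
    f <- tempfile(fileext = ".yaml")
    yaml::write_yaml(lst, f)
    back <- paramsFromList(yaml::read_yaml(f))
    for (sl in slotNames("SyntheticParams"))
      expect_equal(slot(back, sl), slot(p, sl), info = paste(nm, sl))
  }
})

test_that("cohorts have the requested size and length range", {
  p <- syntheticParams(seed = 35L, lengthRange = c(30L, 120L))
  coh <- generateCohort(p, nFragments = 10L)
  expect_length(coh, 10)
  lens <- vapply(coh, fragmentLength, 0L)
  expect_true(all(lens >= 30 & lens <= 120))
  expect_true(all(vapply(coh, function(x)
    identical(channelNames(x), c("platform", "focus")), TRUE)))
})

test_that("rendered images round-trip through extraction", {
  # psf 0, width 1: painting is exactly invertible
  p <- syntheticParams(seed = 36L)
  coh <- generateCohort(p, nFragments = 3L)
  img <- renderImage(coh, psfSigmaPx = 0, background = 5, widthPx = 1)
  prof <- extractProfiles(img$channels, img$traces,
                          backgrounds = c(platform = 5, focus = 5))
  for (f in 1:3)
    expect_equal(intensityMatrix(prof[[f]]),
                 pmax(intensityMatrix(coh[[f]]), 0), tolerance = 1e-9)
})

test_that("zero fragments render to a constant background", {
  img <- renderImage(list(), psfSigmaPx = 1, background = 7)
  expect_true(all(img$channels$platform@pixels == 7))
})

test_that("a too-small canvas is a layout error", {
  p <- syntheticParams(seed = 37L)
  coh <- generateCohort(p, nFragments = 5L)
  expect_error(renderImage(coh, dim = c(10, 10)), "too small")
})

test_that("cohort TSV + ground-truth sidecar land on disk together", {
  p <- getPreset("wt_like"); p@seed <- 38L
  coh <- generateCohort(p, nFragments = 4L)
  f <- tempfile(fileext = ".tsv")
  writeCohort(coh, f, params = p)
  expect_true(file.exists(f))
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$ground_truth$fragment_id, 4)
  expect_equal(truth$params$depletionDepth, 0.7)
  back <- readProfileTable(f)
  expect_length(back, 4)
  expect_equal(intensityMatrix(back[[1]]), intensityMatrix(coh[[1]]),
               tolerance = 1e-12)
})
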