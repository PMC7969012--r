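#' @include AllClasses.R AllGenerics.R
NULL

#' Read a RunConfig from a YAML file
#'
#' Top-level keys mirror the [RunConfig-class] slots (snake_case or
#' camelCase both accepted); unknown keys are an error so typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  camel <- function(nm) gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
  names(y) <- camel(names(y))
  known <- slotNames("RunConfig")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$backgroundMeans)) y$backgroundMeans <- unlist(y$backgroundMeans)
  if (!is.null(y$conditions)) y$conditions <- as.character(unlist(y$conditions))
  if (!is.null(y$columnMap) && !is.null(y$columnMap$channels))
    y$columnMap$channels <- unlist(y$columnMap$channels)
  do.call(runConfig, y)
}

.swapFragment <- function(frag) {
  new("ScaledFragment", s = frag@r, r = frag@s, cellId = frag@cellId,
      fragmentId = frag@fragmentId, condition = frag@condition)
}

## auto curve of the partner channel = auto curve on swapped fragments
.conditionCurves <- function(scaled, cfg) {
  lagSets <- list(main = cfg@xMax)
  curves <- list(
    auto_primary = correlationCurve(scaled, mode = "auto", xMax = cfg@xMax,
                                    estimator = cfg@estimator,
                                    sampleUnit = cfg@sampleUnit),
    auto_partner = correlationCurve(lapply(scaled, .swapFragment),
                                    mode = "auto", xMax = cfg@xMax,
                                    estimator = cfg@estimator,
                                    sampleUnit = cfg@sampleUnit),
    cross = correlationCurve(scaled, mode = "cross", xMax = cfg@xMax,
                             estimator = cfg@estimator,
                             sampleUnit = cfg@sampleUnit))
  if (length(cfg@extraWindow) == 2L) {
    hi <- cfg@extraWindow[2]
    full <- correlationCurve(scaled, mode = "cross", xMax = hi,
                             estimator = cfg@estimator,
                             sampleUnit = cfg@sampleUnit)
    keep <- full@lags >= cfg@extraWindow[1]
    for (sl in c("lags", "values", "sem", "nProducts", "nSamples",
                 "unitMean", "unitVar", "pValues", "degenerate"))
      slot(full, sl) <- slot(full, sl)[keep]
    curves$cross_extra <- full
  }
  curves
}

.loadProfiles <- function(cfg) {
  switch(cfg@mode,
    "profile-table" = {
      if (length(cfg@columnMap))
        importExternalTable(cfg@inputPath, cfg@columnMap)
      else readProfileTable(cfg@inputPath)
    },
    "images" = {
      channels <- readImageChannels(cfg@inputPath)
      traces <- if (grepl("\\.zip$", cfg@tracesPath))
        readRoiSet(cfg@tracesPath)
      else if (grepl("\\.roi$", cfg@tracesPath))
        list(readImageJRoi(cfg@tracesPath))
      else readTraceTable(cfg@tracesPath)
      bg <- if (length(cfg@backgroundMeans)) cfg@backgroundMeans else NULL
      extractProfiles(channels, traces, bg)
    },
    stop("profiles are generated in synthetic mode"))
}

#' @describeIn runPipeline orchestrate a full run.
#'
#' For each condition the pipeline produces the auto-correlation curves
#' of both channels and the cross-correlation curve with per-lag
#' p-values, written as curve TSVs (with JSON sidecars) under
#' `outputDir`, plus the profile table used, optional PNG plots, and a
#' machine-readable `manifest.json` recording the configuration, the
#' seed, package version and an md5 digest of every output file.
#' Reruns with an identical config produce byte-identical tables.
#'
#' In `synthetic` mode the conditions are generator preset names (all
#' presets when empty), each simulated with `nFragments` fragments and
#' a per-condition seed derived from `seed`. In `profile-table` mode
#' profiles come from `inputPath` via [readProfileTable()] (or
#' [importExternalTable()] when a `columnMap` is configured) and are
#' grouped by their condition labels. In `images` mode, channels are
#' read from the TIFF at `inputPath`, traces from `tracesPath`, and
#' per-channel `backgroundMeans` are subtracted.
#' @return (invisibly) list with per-condition curves, output paths and
#'   the manifest.
#' @export
setMethod("runPipeline", "RunConfig", function(config, ...) {
  validObject(config)
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  curvesByCondition <- list()

  if (config@mode == "synthetic") {
    conds <- if (length(config@conditions)) config@conditions
      else names(genotypePresets())
    profileSets <- list()
    for (k in seq_along(conds)) {
      params <- getPreset(conds[k])
      params@seed <- config@seed + (k - 1L)
      params@nFragments <- config@nFragments
      profileSets[[conds[k]]] <-
        generateCohort(params, condition = conds[k])
      tsv <- file.path(config@outputDir,
                       paste0("profiles_", conds[k], ".tsv"))
      writeCohort(profileSets[[conds[k]]], tsv, params)
      outputs <- c(outputs, tsv, paste0(tsv, ".truth.json"))
    }
  } else {
    profiles <- .loadProfiles(config)
    conds0 <- vapply(profiles, function(p) p@condition, "")
    conds <- if (length(config@conditions)) config@conditions
      else unique(conds0)
    profileSets <- lapply(conds, function(cd) profiles[conds0 == cd])
    names(profileSets) <- conds
    tsv <- file.path(config@outputDir, "profiles_used.tsv")
    writeProfileTable(profiles, tsv)
    outputs <- c(outputs, tsv)
  }

  primary <- if (config@mode == "synthetic") "platform" else config@primary
  partner <- if (config@mode == "synthetic") "focus" else config@partner
  for (cd in names(profileSets)) {
    if (!length(profileSets[[cd]]))
      stop("no fragments for condition '", cd, "'")
    scaled <- scaleCohort(profileSets[[cd]], primary, partner)
    curves <- .conditionCurves(scaled, config)
    digest <- unname(tools::md5sum(
      file.path(config@outputDir,
                if (config@mode == "synthetic")
                  paste0("profiles_", cd, ".tsv") else "profiles_used.tsv")))
    for (nm in names(curves)) {
      tsv <- file.path(config@outputDir,
                       sprintf("curve_%s_%s.tsv", cd, nm))
      writeCurveTable(curves[[nm]], tsv, inputDigest = digest)
      outputs <- c(outputs, tsv, paste0(tsv, ".json"))
      if (config@writePlots) {
        png <- file.path(config@outputDir,
                         sprintf("curve_%s_%s.png", cd, nm))
        grDevices::png(png, width = 700, height = 500)
        plotCurve(curves[[nm]],
                  main = sprintf("%s: %s", cd, nm))
        grDevices::dev.off()
        outputs <- c(outputs, png)
      }
    }
    curvesByCondition[[cd]] <- curves
  }

  manifest <- list(
    package = "axiscor",
    version = as.character(utils::packageVersion("axiscor")),
    mode = config@mode, seed = config@seed,
    primary = primary, partner = partner,
    x_max = config@xMax, estimator = config@estimator,
    sample_unit = config@sampleUnit,
    conditions = names(profileSets),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(config@outputDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(curves = curvesByCondition, outputs = outputs,
                 manifest = manifest, manifestPath = manifestPath))
})
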