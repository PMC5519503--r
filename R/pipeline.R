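#' Configuration for a full pipeline run
#'
#' Collects the inputs and settings of one end-to-end analysis. Inputs may
#' be in-memory objects ([RoiTimeSeries-class], [RegionalPetVector-class])
#' or file paths (NIfTI image + atlas pair, or the package's TSV matrix
#' format).
#'
#' @param bold a [RoiTimeSeries-class], a TSV path written by
#'   [writeRegionalMatrix()], or a 4D NIfTI path (then `atlas` is
#'   required).
#' @param atlas optional 3D label NIfTI path/array, required with NIfTI
#'   `bold`.
#' @param petRcps,petSuv optional [RegionalPetVector-class], TSV/NIfTI
#'   paths for the two tracers; association stages run only for the
#'   tracers provided.
#' @param trSeconds sampling interval, needed when `bold` is a bare matrix
#'   TSV.
#' @param scales integer vector of wavelet scales to analyse; default all
#'   supported scales.
#' @param decimationFactor phase decimation factor (default 4).
#' @param designOrder Hilbert-pair design order (default 2).
#' @param thresholdMode `"per_subject"` (cost-efficiency threshold from
#'   this dataset), `"fixed"` (use `fixedThreshold`), or `"group_mean"`
#'   (supply `groupThresholds`, one `ThresholdSpec` per scale).
#' @param fixedThreshold numeric cutoff for `thresholdMode = "fixed"`.
#' @param groupThresholds list of `ThresholdSpec` for
#'   `thresholdMode = "group_mean"`.
#' @param costGrid candidate costs for the cost-efficiency search.
#' @param dynamicMetrics metrics computed per-timepoint (the stability
#'   stage); defaults to all four.
#' @param excludeBoundary drop boundary-affected timepoints from CVs.
#' @param seed top-level seed echoed into the manifest and used for any
#'   stochastic stage.
#' @param outDir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(bold, atlas = NULL, petRcps = NULL,
                           petSuv = NULL, trSeconds = NULL, scales = NULL,
                           decimationFactor = 4L, designOrder = 2L,
                           thresholdMode = c("per_subject", "group_mean",
                                             "fixed"),
                           fixedThreshold = NULL, groupThresholds = NULL,
                           costGrid = seq(0.05, 0.5, by = 0.01),
                           dynamicMetrics = c("clustering_coefficient",
                                              "local_efficiency",
                                              "node_strength",
                                              "betweenness_centrality"),
                           excludeBoundary = TRUE, seed = 1L,
                           outDir = tempfile("phasefc_run_")) {
  thresholdMode <- match.arg(thresholdMode)
  if (thresholdMode == "fixed" && is.null(fixedThreshold))
    stop("'fixedThreshold' required for thresholdMode = \"fixed\"")
  if (thresholdMode == "group_mean" && is.null(groupThresholds))
    stop("'groupThresholds' required for thresholdMode = \"group_mean\"")
  structure(list(bold = bold, atlas = atlas, petRcps = petRcps,
                 petSuv = petSuv, trSeconds = trSeconds, scales = scales,
                 decimationFactor = as.integer(decimationFactor),
                 designOrder = as.integer(designOrder),
                 thresholdMode = thresholdMode,
                 fixedThreshold = fixedThreshold,
                 groupThresholds = groupThresholds, costGrid = costGrid,
                 dynamicMetrics = dynamicMetrics,
                 excludeBoundary = excludeBoundary,
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

#' Run the full phase-synchrony network pipeline
#'
#' Executes every stage on one dataset: multiscale phase decomposition,
#' static and dynamic phase-synchrony connectivity, cost-efficiency
#' thresholding, node metrics, temporal-stability CVs, and (when PET
#' covariates are supplied) the repeated-measures association models with
#' post-hoc correlations. All artifacts are written to `outDir` as
#' delimited tables plus a JSON run manifest; numeric outputs are
#' deterministic given the config (same seed, byte-identical tables).
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param verbose log each stage with timing (default TRUE).
#' @return Invisibly, a list with the in-memory results: `phase`,
#'   `staticFC` (per scale), `thresholds`, `staticMetrics`, `stability`,
#'   `associations`, `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  log <- function(...) if (verbose)
    message(sprintf("[%6.1fs] ", as.numeric(Sys.time() - t0, "secs")), ...)

  roi <- loadBoldInput(config)
  pet <- loadPetInputs(config, roi)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  filters <- designHwpFilters(config$designOrder)
  nT <- ncol(boldValues(roi))
  nScalesMax <- maxScales(nT)
  scales <- if (is.null(config$scales)) seq_len(nScalesMax)
            else as.integer(config$scales)
  if (any(scales < 1L) || any(scales > nScalesMax))
    stop("requested scales outside 1..", nScalesMax)

  log("phase decomposition: ", nRegions(roi), " regions, ",
      length(scales), " scales")
  phase <- multiscalePhase(roi, filters, nScales = nScalesMax,
                           decimationFactor = config$decimationFactor)

  bandJson <- scaleBands(phase)[scales, ]
  jsonlite::write_json(bandJson, file.path(config$outDir, "bands.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  staticFCs <- list()
  thresholds <- list()
  staticRows <- list()
  stabilityRows <- list()
  for (s in scales) {
    log("scale ", s, ": connectivity and metrics")
    fc <- staticFC(phase, scaleIndex = s)
    staticFCs[[as.character(s)]] <- fc
    writeRegionalMatrix(fcMatrix(fc),
                        file.path(config$outDir,
                                  sprintf("static_fc_scale%02d.tsv", s)),
                        regionIds = regionIds(roi))
    spec <- switch(config$thresholdMode,
      per_subject = costEfficiencyThreshold(fc, config$costGrid),
      fixed = structure(list(scaleIndex = s,
                             thresholdValue = config$fixedThreshold,
                             costAtThreshold = NA_real_,
                             efficiency = NA_real_,
                             costEfficiency = NA_real_,
                             provenance = "fixed", table = NULL),
                        class = "ThresholdSpec"),
      group_mean = config$groupThresholds[[as.character(s)]])
    if (is.null(spec)) stop("no group threshold supplied for scale ", s)
    thresholds[[as.character(s)]] <- spec

    staticRows[[as.character(s)]] <- computeMetricTable(fc, spec)

    sync <- dynamicFC(phase, scaleIndex = s)
    dynTab <- computeMetricTable(sync, spec,
                                 metrics = config$dynamicMetrics)
    bnd <- if (config$excludeBoundary) boundaryMask(phase)[s, ] else NULL
    stabilityRows[[as.character(s)]] <- stabilityTable(dynTab, bnd)
  }
  staticMetrics <- do.call(rbind, staticRows)
  stability <- do.call(rbind, stabilityRows)
  rownames(staticMetrics) <- rownames(stability) <- NULL
  utils::write.table(staticMetrics,
                     file.path(config$outDir, "node_metrics_static.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stability,
                     file.path(config$outDir, "node_metric_cv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  associations <- list()
  covs <- Filter(Negate(is.null), list(rCPS = pet$rcps, SUV = pet$suv))
  if (length(covs)) {
    log("association models (", paste(names(covs), collapse = " + "), ")")
    for (m in unique(staticMetrics$metric)) {
      Y <- metricByScale(staticMetrics, m)
      associations[[paste0("static_", m)]] <-
        rmGlm(Y, unname(covs), metric = m, posthoc = TRUE,
              familySize = 4L * ncol(Y))
    }
    for (m in unique(stability$metric)) {
      Ycv <- metricByScale(stability, m)
      if (anyNA(Ycv)) next  # degenerate CVs at some scale
      associations[[paste0("cv_", m)]] <-
        rmGlm(Ycv, unname(covs), metric = paste0("CV(", m, ")"),
              posthoc = TRUE, familySize = 4L * ncol(Ycv))
    }
    assocTab <- do.call(rbind, lapply(names(associations), function(nm) {
      cbind(model = nm, assocEffects(associations[[nm]]))
    }))
    utils::write.table(assocTab,
                       file.path(config$outDir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "phasefc",
    version = as.character(utils::packageVersion("phasefc")),
    rVersion = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    regionOrder = regionIds(roi),
    trSeconds = trSeconds(roi),
    nTimepoints = nT,
    scales = scales,
    decimationFactor = config$decimationFactor,
    designOrder = config$designOrder,
    thresholdMode = config$thresholdMode,
    thresholds = lapply(thresholds, function(x)
      x[c("scaleIndex", "thresholdValue", "costAtThreshold", "provenance")]),
    elapsedSeconds = as.numeric(Sys.time() - t0, "secs"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done; outputs in ", config$outDir)

  invisible(list(phase = phase, staticFC = staticFCs,
                 thresholds = thresholds, staticMetrics = staticMetrics,
                 stability = stability, associations = associations,
                 manifest = manifest))
}

loadBoldInput <- function(config) {
  b <- config$bold
  if (is(b, "RoiTimeSeries")) return(b)
  if (is.character(b) && grepl("\\.tsv$", b)) {
    if (is.null(config$trSeconds))
      stop("'trSeconds' required with TSV bold input")
    rm <- readRegionalMatrix(b)
    return(roiTimeSeries(rm$matrix, regionIds = rm$regionIds,
                         trSeconds = config$trSeconds))
  }
  if (is.null(config$atlas))
    stop("configuration error: NIfTI bold input requires an atlas")
  extractRoiTimeSeries(b, config$atlas, trSeconds = config$trSeconds)
}

loadPetInputs <- function(config, roi) {
  loadOne <- function(x, tr) {
    if (is.null(x)) return(NULL)
    if (is(x, "RegionalPetVector")) return(x)
    if (is.character(x) && grepl("\\.tsv$", x)) {
      rm <- readRegionalMatrix(x)
      return(regionalPetVector(rm$matrix[, 1L], tr,
                               regionIds = rm$regionIds))
    }
    averagePetByRegion(x, config$atlas, tracer = tr)
  }
  out <- list(rcps = loadOne(config$petRcps, "rCPS"),
              suv = loadOne(config$petSuv, "SUV"))
  for (v in Filter(Negate(is.null), out)) {
    if (!identical(regionIds(v), regionIds(roi)))
      stop("PET region order does not match the BOLD region order")
  }
  out
}
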