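#' @import methods
NULL

#' Region-labelled BOLD time-series matrix
#'
#' Container for parcellated resting-state BOLD data: one row per atlas
#' region, one column per acquired volume, with the repetition time (TR)
#' recording the sampling interval.
#'
#' @slot values numeric matrix, `n_regions x n_timepoints`; arbitrary signal
#'   units.
#' @slot regionIds integer vector of atlas labels, one per row, unique and in
#'   the row order of `values`.
#' @slot trSeconds positive scalar, sampling interval in seconds.
#'
#' @seealso [roiTimeSeries()], [extractRoiTimeSeries()]
#' @export
setClass("RoiTimeSeries",
  representation(
    values = "matrix",
    regionIds = "integer",
    trSeconds = "numeric"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 regions")
  if (ncol(v) < 64L) msg <- c(msg, "need at least 64 timepoints")
  if (length(object@regionIds) != nrow(v))
    msg <- c(msg, "'regionIds' length must equal nrow(values)")
  if (anyDuplicated(object@regionIds))
    msg <- c(msg, "'regionIds' must be unique")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "'trSeconds' must be a positive scalar")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "'values' must contain only finite entries")
  if (length(msg)) msg else TRUE
})

#' Regional PET covariate vector
#'
#' One value per atlas region for a single PET tracer: either rCPS (regional
#' cerebral protein synthesis rate, nmol/g/min, from L-[1-11C]leucine) or SUV
#' (standardized uptake value, dimensionless, from [18F]FDG). Region order
#' must match the paired [RoiTimeSeries-class].
#'
#' @slot values strictly positive numeric vector, one entry per region.
#' @slot tracer `"rCPS"` or `"SUV"`.
#' @slot regionIds integer atlas labels matching `values`.
#'
#' @seealso [regionalPetVector()], [averagePetByRegion()]
#' @export
setClass("RegionalPetVector",
  representation(
    values = "numeric",
    tracer = "character",
    regionIds = "integer"
  )
)

setValidity("RegionalPetVector", function(object) {
  msg <- character()
  if (!object@tracer %in% c("rCPS", "SUV"))
    msg <- c(msg, "'tracer' must be \"rCPS\" or \"SUV\"")
  if (length(object@values) != length(object@regionIds))
    msg <- c(msg, "'values' and 'regionIds' lengths differ")
  if (anyDuplicated(object@regionIds))
    msg <- c(msg, "'regionIds' must be unique")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    msg <- c(msg, "'values' must be finite and strictly positive")
  if (length(msg)) msg else TRUE
})

#' Approximate Hilbert wavelet pair filter bank
#'
#' Two orthonormal real wavelet filter banks whose scaling filters differ by
#' an approximate half-sample delay, so that the combined complex wavelet
#' psi_h + i psi_g is approximately analytic (energy concentrated on positive
#' frequencies). Built by the common-factor construction: a maximally flat
#' (Thiran) half-delay factor shared with its time reverse, a factor of
#' vanishing moments, and a spectral factor solved from the orthonormality
#' (halfband) conditions.
#'
#' @slot h,g numeric wavelet (highpass) filters of the two banks.
#' @slot scalingH,scalingG matching scaling (lowpass) filters; each sums to
#'   sqrt(2).
#' @slot designOrder integer, the design order used.
#' @slot quality numeric, fraction of energy of the combined complex wavelet
#'   at negative frequencies (smaller is better; an exact Hilbert pair would
#'   give 0).
#'
#' @seealso [designHwpFilters()]
#' @export
setClass("HwpFilterPair",
  representation(
    h = "numeric",
    g = "numeric",
    scalingH = "numeric",
    scalingG = "numeric",
    designOrder = "integer",
    quality = "numeric"
  )
)

setValidity("HwpFilterPair", function(object) {
  msg <- character()
  if (length(object@h) != length(object@g))
    msg <- c(msg, "'h' and 'g' must have equal length")
  if (abs(sum(object@scalingH) - sqrt(2)) > 1e-8)
    msg <- c(msg, "scalingH must sum to sqrt(2)")
  if (abs(sum(object@scalingG) - sqrt(2)) > 1e-8)
    msg <- c(msg, "scalingG must sum to sqrt(2)")
  if (length(msg)) msg else TRUE
})

#' Per-scale instantaneous phase of band-limited analytic signals
#'
#' Phases (radians, in (-pi, pi]) of the analytic wavelet coefficients of
#' each region at each dyadic scale, after anti-aliased decimation.
#'
#' @slot phases numeric array `n_scales x n_regions x n_decimated_timepoints`.
#' @slot bands data.frame of band metadata, one row per scale: nominal
#'   (printed-convention) edges `fLo`/`fHi` and physical passband edges
#'   `fLoPass`/`fHiPass`, in Hz, plus flags for bands outside the reliably
#'   resolved range. See [scaleBandTable()].
#' @slot decimationFactor integer decimation factor applied to the phase
#'   series.
#' @slot trSeconds original sampling interval, seconds.
#' @slot regionIds integer atlas labels.
#' @slot boundaryMask logical matrix `n_scales x n_decimated_timepoints`;
#'   TRUE where a coefficient is affected by circular boundary handling.
#'
#' @seealso [multiscalePhase()]
#' @export
setClass("MultiscalePhase",
  representation(
    phases = "array",
    bands = "data.frame",
    decimationFactor = "integer",
    trSeconds = "numeric",
    regionIds = "integer",
    boundaryMask = "matrix"
  )
)

setValidity("MultiscalePhase", function(object) {
  msg <- character()
  p <- object@phases
  if (length(dim(p)) != 3L) msg <- c(msg, "'phases' must be a 3-d array")
  if (any(!is.finite(p))) msg <- c(msg, "'phases' must be finite")
  if (length(p) && (max(p) > pi + 1e-12 || min(p) <= -pi - 1e-12))
    msg <- c(msg, "'phases' must lie in (-pi, pi]")
  if (nrow(object@bands) != dim(p)[1L])
    msg <- c(msg, "'bands' must have one row per scale")
  if (length(object@regionIds) != dim(p)[2L])
    msg <- c(msg, "'regionIds' length must match phase array")
  if (length(msg)) msg else TRUE
})

#' Time-resolved pairwise phase-synchrony matrices
#'
#' The pairwise Kuramoto order parameter R_xy(t) for every region pair at
#' every (decimated) timepoint of one wavelet scale. Values lie in [0, 1];
#' each time slice is symmetric with unit diagonal.
#'
#' @slot r numeric array `n_regions x n_regions x n_timepoints`.
#' @slot scaleIndex integer, which wavelet scale this belongs to.
#' @slot regionIds integer atlas labels.
#'
#' @seealso [dynamicFC()], [staticFC()]
#' @export
setClass("SyncSeries",
  representation(
    r = "array",
    scaleIndex = "integer",
    regionIds = "integer"
  )
)

setValidity("SyncSeries", function(object) {
  msg <- character()
  d <- dim(object@r)
  if (length(d) != 3L || d[1L] != d[2L])
    msg <- c(msg, "'r' must be a square-sliced 3-d array")
  if (length(object@r) &&
      (min(object@r) < -1e-12 || max(object@r) > 1 + 1e-12))
    msg <- c(msg, "synchrony values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Time-averaged (static) functional connectivity matrix
#'
#' Temporal mean of the pairwise synchrony series at one wavelet scale:
#' symmetric, unit diagonal, entries in [0, 1].
#'
#' @slot matrix numeric `n_regions x n_regions` matrix.
#' @slot scaleIndex integer scale index.
#' @slot regionIds integer atlas labels.
#'
#' @seealso [staticFC()]
#' @export
setClass("StaticFC",
  representation(
    matrix = "matrix",
    scaleIndex = "integer",
    regionIds = "integer"
  )
)

setValidity("StaticFC", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "'matrix' must be square")
  if (length(m) && max(abs(m - t(m))) > 1e-10)
    msg <- c(msg, "'matrix' must be symmetric")
  if (length(m) && (min(m) < -1e-12 || max(m) > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Repeated-measures association between network metrics and PET covariates
#'
#' Result of a repeated-measures general linear model with regions as units,
#' wavelet scale as the within-unit factor, and one or two regional PET
#' covariates: per-covariate main-effect F tests, covariate-by-scale
#' interaction F tests with Greenhouse-Geisser correction, Mauchly's
#' sphericity test, and optional post-hoc per-scale (partial) correlations.
#'
#' @slot metric character, name of the network metric analysed.
#' @slot covariates character vector of covariate (tracer) names.
#' @slot effects data.frame, one row per tested effect: `effect`, `F`,
#'   `df1`, `df2`, `p`, and for interactions the epsilon-corrected
#'   `df1GG`, `df2GG`, `pGG`.
#' @slot ggEpsilon Greenhouse-Geisser epsilon for the within factor.
#' @slot mauchlyW,mauchlyP Mauchly sphericity statistic and p-value.
#' @slot posthoc data.frame of per-scale (partial) Pearson correlations, or a
#'   zero-row data.frame when not requested.
#'
#' @seealso [rmGlm()], [posthocCorrelations()]
#' @export
setClass("AssociationResult",
  representation(
    metric = "character",
    covariates = "character",
    effects = "data.frame",
    ggEpsilon = "numeric",
    mauchlyW = "numeric",
    mauchlyP = "numeric",
    posthoc = "data.frame"
  )
)
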