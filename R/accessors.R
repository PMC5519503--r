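#' Constructors and accessors for the core data containers
#'
#' `roiTimeSeries()` and `regionalPetVector()` build validated objects from
#' plain R structures; the accessor generics extract slots without touching
#' the internal representation.
#'
#' @param values numeric matrix (regions x timepoints) or numeric vector.
#' @param regionIds integer atlas labels, one per region; defaults to
#'   `seq_len(n)`.
#' @param trSeconds sampling interval in seconds.
#' @param tracer `"rCPS"` or `"SUV"`.
#' @param x an object.
#'
#' @return `roiTimeSeries()` a [RoiTimeSeries-class]; `regionalPetVector()` a
#'   [RegionalPetVector-class]; accessors return the corresponding slot.
#'
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(5 * 128), 5), trSeconds = 0.72)
#' nRegions(ts)
#' trSeconds(ts)
#'
#' @name accessors
#' @aliases roiTimeSeries regionalPetVector
NULL

#' @rdname accessors
#' @export
roiTimeSeries <- function(values, regionIds = seq_len(nrow(values)),
                          trSeconds = 0.72) {
  storage.mode(values) <- "double"
  new("RoiTimeSeries", values = values,
      regionIds = as.integer(regionIds), trSeconds = as.numeric(trSeconds))
}

#' @rdname accessors
#' @export
regionalPetVector <- function(values, tracer = c("rCPS", "SUV"),
                              regionIds = seq_along(values)) {
  tracer <- match.arg(tracer)
  new("RegionalPetVector", values = as.numeric(values), tracer = tracer,
      regionIds = as.integer(regionIds))
}

#' @rdname accessors
#' @export
setMethod("regionIds", "RoiTimeSeries", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "RegionalPetVector", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "MultiscalePhase", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "SyncSeries", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "StaticFC", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(x) x@trSeconds)
#' @rdname accessors
#' @export
setMethod("trSeconds", "MultiscalePhase", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("nRegions", "RoiTimeSeries", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nRegions", "RegionalPetVector", function(x) length(x@values))
#' @rdname accessors
#' @export
setMethod("nRegions", "MultiscalePhase", function(x) dim(x@phases)[2L])
#' @rdname accessors
#' @export
setMethod("nRegions", "StaticFC", function(x) nrow(x@matrix))

#' @rdname accessors
#' @export
setMethod("tracer", "RegionalPetVector", function(x) x@tracer)

#' @rdname accessors
#' @export
setMethod("scaleIndex", "SyncSeries", function(x) x@scaleIndex)
#' @rdname accessors
#' @export
setMethod("scaleIndex", "StaticFC", function(x) x@scaleIndex)

#' @rdname accessors
#' @export
setMethod("fcMatrix", "StaticFC", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("syncValues", "SyncSeries", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("phaseArray", "MultiscalePhase", function(x) x@phases)

#' @rdname accessors
#' @export
setMethod("scaleBands", "MultiscalePhase", function(x) x@bands)

#' @rdname accessors
#' @export
setMethod("boundaryMask", "MultiscalePhase", function(x) x@boundaryMask)

#' Extract values from region-level containers
#'
#' @param x a [RoiTimeSeries-class] or [RegionalPetVector-class].
#' @return numeric matrix or vector of values.
#' @export
petValues <- function(x) {
  stopifnot(is(x, "RegionalPetVector"))
  x@values
}

#' @rdname petValues
#' @export
boldValues <- function(x) {
  stopifnot(is(x, "RoiTimeSeries"))
  x@values
}

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d regions x %d timepoints, TR = %.3g s (%.1f min)\n",
              nrow(object@values), ncol(object@values), object@trSeconds,
              ncol(object@values) * object@trSeconds / 60))
  cat(" region labels:", paste(utils::head(object@regionIds, 6), collapse = " "),
      if (length(object@regionIds) > 6) "...\n" else "\n")
})

setMethod("show", "RegionalPetVector", function(object) {
  cat(sprintf("RegionalPetVector (%s): %d regions, range [%.3g, %.3g]%s\n",
              object@tracer, length(object@values), min(object@values),
              max(object@values),
              if (object@tracer == "rCPS") " nmol/g/min" else " (SUV)"))
})

setMethod("show", "HwpFilterPair", function(object) {
  cat(sprintf("HwpFilterPair: design order %d, filter length %d\n",
              object@designOrder, length(object@h)))
  cat(sprintf(" analyticity: %.3g%% of combined-wavelet energy at negative frequencies\n",
              100 * object@quality))
})

setMethod("show", "MultiscalePhase", function(object) {
  d <- dim(object@phases)
  cat(sprintf("MultiscalePhase: %d scales x %d regions x %d timepoints (decimated x%d)\n",
              d[1], d[2], d[3], object@decimationFactor))
  b <- object@bands
  cat(sprintf(" passbands: %.4g-%.4g Hz (scale %d) ... %.4g-%.4g Hz (scale %d)\n",
              b$fLoPass[1], b$fHiPass[1], b$scale[1],
              b$fLoPass[nrow(b)], b$fHiPass[nrow(b)], b$scale[nrow(b)]))
})

setMethod("show", "SyncSeries", function(object) {
  d <- dim(object@r)
  cat(sprintf("SyncSeries (scale %d): %d x %d regions x %d timepoints, mean R = %.3f\n",
              object@scaleIndex, d[1], d[2], d[3],
              mean(object@r[row(diag(d[1])) < col(diag(d[1]))])))
})

setMethod("show", "StaticFC", function(object) {
  m <- object@matrix
  off <- m[upper.tri(m)]
  cat(sprintf("StaticFC (scale %d): %d regions, off-diagonal synchrony %.3f [%.3f, %.3f]\n",
              object@scaleIndex, nrow(m), mean(off), min(off), max(off)))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult for '%s' (covariates: %s)\n", object@metric,
              paste(object@covariates, collapse = " + ")))
  cat(sprintf(" Mauchly W = %.4f (p = %.3g), GG epsilon = %.4f\n",
              object@mauchlyW, object@mauchlyP, object@ggEpsilon))
  print(object@effects, digits = 4, row.names = FALSE)
  if (nrow(object@posthoc))
    cat(sprintf(" post-hoc: %d per-scale correlations (%d significant after Bonferroni)\n",
                nrow(object@posthoc), sum(object@posthoc$significant)))
})

#' Accessors for association results
#'
#' @param x an [AssociationResult-class].
#' @return `assocEffects()` the effect table; `ggEpsilon()` and `mauchlyW()`
#'   the sphericity quantities; `posthocTable()` the per-scale correlation
#'   table.
#' @export
assocEffects <- function(x) {
  stopifnot(is(x, "AssociationResult"))
  x@effects
}

#' @rdname assocEffects
#' @export
assocGGEpsilon <- function(x) {
  stopifnot(is(x, "AssociationResult"))
  x@ggEpsilon
}

#' @rdname assocEffects
#' @export
assocMauchlyW <- function(x) {
  stopifnot(is(x, "AssociationResult"))
  x@mauchlyW
}

#' @rdname assocEffects
#' @export
posthocTable <- function(x) {
  stopifnot(is(x, "AssociationResult"))
  x@posthoc
}

#' Filters of a Hilbert wavelet pair
#'
#' @param x an [HwpFilterPair-class].
#' @return `hwpFilters()` returns a list with components `h`, `g` (wavelet
#'   filters) and `scalingH`, `scalingG`; `hwpQuality()` the negative-frequency
#'   energy fraction of the combined complex wavelet.
#' @export
hwpFilters <- function(x) {
  stopifnot(is(x, "HwpFilterPair"))
  list(h = x@h, g = x@g, scalingH = x@scalingH, scalingG = x@scalingG)
}

#' @rdname hwpFilters
#' @export
hwpQuality <- function(x) {
  stopifnot(is(x, "HwpFilterPair"))
  x@quality
}
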