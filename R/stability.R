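#' Temporal coefficient of variation
#'
#' Variability of a node metric across dynamic-connectivity timepoints:
#' population standard deviation divided by mean. The population (divide by
#' n) convention is used; for the ~300 decimated timepoints of a 15-minute
#' acquisition the sample/population distinction is negligible, but fixing
#' it makes results bit-reproducible. A series whose mean is below 1e-12 in
#' absolute value has no meaningful CV and returns `NA_real_`.
#'
#' @param metricSeries numeric vector of one node metric over time,
#'   length >= 2.
#' @return scalar CV (>= 0 for nonnegative metrics), or `NA_real_` when the
#'   mean is degenerate.
#' @examples
#' temporalCV(c(1, 3))  # population sd 1, mean 2 -> 0.5
#' @export
temporalCV <- function(metricSeries) {
  n <- length(metricSeries)
  if (n < 2L) stop("need at least 2 timepoints for a CV")
  m <- mean(metricSeries)
  if (abs(m) < 1e-12) return(NA_real_)
  sdp <- sqrt(sum((metricSeries - m)^2) / n)
  sdp / m
}

#' Stability table from a dynamic node-metric table
#'
#' Collapses a dynamic (per-timepoint) metric table to one temporal CV per
#' region, metric and scale. Timepoints flagged as wavelet/FIR
#' boundary-affected can be excluded, since circular-boundary transients
#' inflate the variance estimate.
#'
#' @param dynTable long-format data.frame from [computeMetricTable()] on a
#'   [SyncSeries-class] (columns region, scale, timepoint, metric, value).
#' @param boundary optional logical vector over timepoints (TRUE =
#'   boundary-affected, excluded), e.g. a row of [boundaryMask()].
#' @return data.frame: `region`, `scale`, `metric`, `cv`,
#'   `nTimepointsUsed`.
#' @export
stabilityTable <- function(dynTable, boundary = NULL) {
  stopifnot(all(c("region", "scale", "timepoint", "metric", "value") %in%
                names(dynTable)))
  if (!is.null(boundary)) {
    keep <- which(!boundary)
    if (length(keep) < 2L)
      stop("fewer than 2 non-boundary timepoints")
    dynTable <- dynTable[dynTable$timepoint %in% keep, ]
  }
  agg <- stats::aggregate(value ~ region + scale + metric, data = dynTable,
                          FUN = function(v) c(cv = temporalCV(v),
                                              n = length(v)))
  out <- data.frame(region = agg$region, scale = agg$scale,
                    metric = agg$metric, cv = agg$value[, "cv"],
                    nTimepointsUsed = as.integer(agg$value[, "n"]))
  out[order(out$metric, out$region), ]
}

#' Average metric or stability tables across subjects
#'
#' Elementwise arithmetic mean of per-subject tables with identical layout
#' (same regions, scales, metrics in the same order), producing the
#' population-average table used by the association stage. Flagged missing
#' CVs (`NA`) are ignored, with the contributing count reported.
#'
#' @param tables list of data.frames sharing the same key columns and one
#'   value column (`value` or `cv`).
#' @return data.frame with the shared keys, the averaged value column, and
#'   `nSubjects` (how many non-missing values entered each mean).
#' @export
subjectAverage <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  valueCol <- intersect(c("value", "cv"), names(tables[[1L]]))[1L]
  if (is.na(valueCol)) stop("no 'value' or 'cv' column found")
  keyCols <- setdiff(names(tables[[1L]]), c(valueCol, "nTimepointsUsed"))
  ref <- tables[[1L]][keyCols]
  for (tb in tables[-1L]) {
    if (!identical(dim(tb[keyCols]), dim(ref)) ||
        !identical(tb[keyCols], ref))
      stop("tables have mismatched shape or key ordering")
  }
  vals <- vapply(tables, function(tb) tb[[valueCol]],
                 numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  out <- ref
  out[[valueCol]] <- rowMeans(vals, na.rm = TRUE)
  out[[valueCol]][is.nan(out[[valueCol]])] <- NA_real_
  out$nSubjects <- as.integer(rowSums(!is.na(vals)))
  out
}

#' Reshape a long metric table to a regions-by-scales matrix
#'
#' Convenience for feeding [rmGlm()]: extracts one metric from a long
#' table and pivots it to the `n_regions x n_scales` matrix the
#' repeated-measures model expects.
#'
#' @param table long-format data.frame with columns `region`, `scale`,
#'   `metric` and a value column (`value` or `cv`).
#' @param metric which metric to extract.
#' @return numeric matrix with regions as rows (named by region id) and
#'   scales as columns.
#' @export
metricByScale <- function(table, metric) {
  valueCol <- intersect(c("value", "cv"), names(table))[1L]
  sub <- table[table$metric == metric, ]
  if (!nrow(sub)) stop("metric '", metric, "' not present")
  regions <- sort(unique(sub$region))
  scales <- sort(unique(sub$scale))
  m <- matrix(NA_real_, length(regions), length(scales),
              dimnames = list(regions, scales))
  m[cbind(match(sub$region, regions), match(sub$scale, scales))] <-
    sub[[valueCol]]
  m
}
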