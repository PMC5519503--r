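#' Pairwise Kuramoto order parameter
#'
#' Time-resolved phase synchrony between two phase series, the modulus of
#' the two-oscillator Kuramoto order parameter:
#' `R(t) = |(exp(i*th_x) + exp(i*th_y))/2| = |cos((th_x - th_y)/2)|`.
#' R is 1 for identical phases, 0 in antiphase, and depends only on the
#' phase difference.
#'
#' @param thetaX,thetaY numeric phase series of equal length, radians.
#' @return numeric synchrony series in [0, 1].
#' @examples
#' pairwiseKuramoto(rep(0, 4), rep(pi, 4))      # all 0
#' pairwiseKuramoto(rep(0, 4), rep(pi / 2, 4))  # all sqrt(2)/2
#' @export
pairwiseKuramoto <- function(thetaX, thetaY) {
  if (length(thetaX) != length(thetaY))
    stop("phase series lengths differ (", length(thetaX), " vs ",
         length(thetaY), ")")
  if (any(!is.finite(thetaX)) || any(!is.finite(thetaY)))
    stop("phases must be finite")
  abs(cos((thetaX - thetaY) / 2))
}

#' Time-resolved functional connectivity at one wavelet scale
#'
#' Applies the pairwise Kuramoto order parameter to every region pair at
#' every timepoint of one scale of a [MultiscalePhase-class], producing a
#' time-dependent synchrony matrix stack. Symmetry and unit diagonal hold by
#' construction.
#'
#' @param phases a [MultiscalePhase-class].
#' @param scaleIndex which scale to use.
#' @return A [SyncSeries-class].
#' @export
dynamicFC <- function(phases, scaleIndex) {
  stopifnot(is(phases, "MultiscalePhase"))
  d <- dim(phases@phases)
  if (scaleIndex < 1L || scaleIndex > d[1L])
    stop("'scaleIndex' out of range 1..", d[1L])
  nr <- d[2L]; nt <- d[3L]
  r <- array(0, dim = c(nr, nr, nt))
  th <- phases@phases[scaleIndex, , , drop = TRUE]
  if (is.null(dim(th))) th <- matrix(th, nrow = nr)
  for (t in seq_len(nt)) {
    dtheta <- outer(th[, t], th[, t], "-")
    r[, , t] <- abs(cos(dtheta / 2))
  }
  new("SyncSeries", r = r, scaleIndex = as.integer(scaleIndex),
      regionIds = phases@regionIds)
}

#' Static (time-averaged) functional connectivity
#'
#' Temporal mean of a pairwise synchrony series, yielding one symmetric
#' unit-diagonal matrix per scale. Under fully independent uniform phases
#' the expected off-diagonal value is `E|cos(U/2)| = 2/pi`, which serves as
#' the chance floor of this connectivity measure.
#'
#' @param sync a [SyncSeries-class], or a [MultiscalePhase-class] together
#'   with `scaleIndex` (computed without materializing the full stack).
#' @param scaleIndex scale to use when `sync` is a [MultiscalePhase-class].
#' @param excludeBoundary logical; when a [MultiscalePhase-class] is given,
#'   drop timepoints flagged as wavelet/FIR boundary-affected before
#'   averaging (default FALSE, averaging all timepoints).
#' @return A [StaticFC-class].
#' @export
staticFC <- function(sync, scaleIndex = NULL, excludeBoundary = FALSE) {
  if (is(sync, "MultiscalePhase")) {
    stopifnot(!is.null(scaleIndex))
    th <- sync@phases[scaleIndex, , , drop = TRUE]
    if (is.null(dim(th))) th <- matrix(th, nrow = dim(sync@phases)[2L])
    if (excludeBoundary) {
      keep <- !sync@boundaryMask[scaleIndex, ]
      if (sum(keep) >= 2L) th <- th[, keep, drop = FALSE]
    }
    # mean_t |cos((th_i - th_j)/2)| accumulated per timepoint
    nr <- nrow(th)
    acc <- matrix(0, nr, nr)
    for (t in seq_len(ncol(th))) {
      dtheta <- outer(th[, t], th[, t], "-")
      acc <- acc + abs(cos(dtheta / 2))
    }
    m <- acc / ncol(th)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    return(new("StaticFC", matrix = m,
               scaleIndex = as.integer(scaleIndex),
               regionIds = sync@regionIds))
  }
  stopifnot(is(sync, "SyncSeries"))
  m <- apply(sync@r, c(1L, 2L), mean)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  new("StaticFC", matrix = m, scaleIndex = sync@scaleIndex,
      regionIds = sync@regionIds)
}
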