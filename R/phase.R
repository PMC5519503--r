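#' Instantaneous phase of analytic coefficients
#'
#' Elementwise argument of complex analytic wavelet coefficients, in
#' (-pi, pi]. Exact zeros have no defined phase; they are set to 0 by
#' convention with a warning.
#'
#' @param analytic complex vector (or array) of analytic coefficients.
#' @return numeric phase of the same shape, radians in (-pi, pi].
#' @examples
#' extractPhase(complex(real = 0, imaginary = 1))  # pi/2
#' @export
extractPhase <- function(analytic) {
  if (all(analytic == 0))
    stop("analytic coefficients are identically zero; phase undefined")
  ph <- Arg(analytic)
  zero <- analytic == 0
  if (any(zero)) {
    warning(sum(zero), " zero coefficient(s): phase set to 0 by convention")
    ph[zero] <- 0
  }
  # Arg returns -pi for negative reals; fold onto (-pi, pi]
  ph[ph <= -pi] <- pi
  ph
}

#' Decimate a phase series with an anti-aliasing FIR filter
#'
#' Reduces the sampling rate of an instantaneous-phase series by an integer
#' factor. To avoid wrap-around artefacts at the +/-pi boundary the
#' smoothing is applied to the unit-modulus complex representation
#' `exp(i*theta)` rather than to raw angles: a linear-phase lowpass FIR
#' (cutoff 0.8 of the decimated Nyquist, length `8*factor + 1`) is run
#' forward-backward (zero net phase) over the real and imaginary parts,
#' every `factor`-th sample is kept, and the angle is re-extracted.
#'
#' @param phase numeric phase series in radians.
#' @param factor integer decimation factor, >= 1; the series must be at
#'   least `8 * factor` samples long.
#' @return numeric phase series of length `floor(length(phase)/factor)`, in
#'   (-pi, pi].
#' @examples
#' th <- rep(pi / 4, 1200)
#' length(decimatePhase(th, 4))  # 300
#' @export
decimatePhase <- function(phase, factor = 4L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1")
  n <- length(phase)
  if (n < 8L * factor)
    stop("'factor' too large: need length >= ", 8L * factor)
  if (factor == 1L) return(phase)
  z <- exp(1i * phase)
  fir <- signal::fir1(8L * factor, 0.8 / factor)
  re <- signal::filtfilt(fir, Re(z))
  im <- signal::filtfilt(fir, Im(z))
  keep <- seq(1L, n, by = factor)[seq_len(n %/% factor)]
  out <- atan2(im[keep], re[keep])
  out[out <= -pi] <- pi
  out
}

#' Multiscale instantaneous phase of regional BOLD series
#'
#' Full band-limited phase decomposition of a parcellated BOLD dataset:
#' each regional series is decomposed by the maximal-overlap wavelet packet
#' transform on an approximate Hilbert wavelet pair
#' ([modwtPacketDecompose()]), the instantaneous phase of the analytic
#' coefficients is extracted per scale, and the phase series are decimated
#' ([decimatePhase()]).
#'
#' @param roi a [RoiTimeSeries-class].
#' @param filters an [HwpFilterPair-class]; default design order 2.
#' @param nScales number of wavelet scales; default the maximum supported
#'   (11 for a 1200-volume acquisition).
#' @param decimationFactor integer, default 4.
#'
#' @return A [MultiscalePhase-class].
#'
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(4 * 256), 4), trSeconds = 0.72)
#' mp <- multiscalePhase(ts, nScales = 6, decimationFactor = 4)
#' dim(phaseArray(mp))  # 6 x 4 x 64
#'
#' @export
multiscalePhase <- function(roi, filters = designHwpFilters(2L),
                            nScales = maxScales(ncol(boldValues(roi))),
                            decimationFactor = 4L) {
  stopifnot(is(roi, "RoiTimeSeries"), is(filters, "HwpFilterPair"))
  x <- t(boldValues(roi))                 # timepoints x regions
  n <- nrow(x)
  nr <- ncol(x)
  if (nScales < 2L || nScales > maxScales(n))
    stop("'nScales' must be in 2..", maxScales(n))
  decimationFactor <- as.integer(decimationFactor)
  nd <- n %/% decimationFactor

  dh <- modwtForward(x, filters@scalingH, filters@h, nScales - 1L)
  dg <- modwtForward(x, filters@scalingG, filters@g, nScales - 1L)

  phases <- array(0, dim = c(nScales, nr, nd))
  for (j in seq_len(nScales)) {
    if (j < nScales) {
      re <- dh$details[[j]]; im <- dg$details[[j]]
    } else {
      re <- dh$smooth; im <- dg$smooth
    }
    th <- atan2(im, re)                   # timepoints x regions
    for (r in seq_len(nr))
      phases[j, r, ] <- decimatePhase(th[, r], decimationFactor)
  }
  phases[phases <= -pi] <- pi

  bnd <- boundaryFlags(n, nScales, length(filters@h))
  bmask <- t(vapply(bnd, function(b) {
    nb <- sum(b)
    seq_len(nd) <= ceiling(nb / decimationFactor)
  }, logical(nd)))

  new("MultiscalePhase", phases = phases,
      bands = scaleBandTable(nScales, trSeconds(roi)),
      decimationFactor = decimationFactor, trSeconds = trSeconds(roi),
      regionIds = regionIds(roi), boundaryMask = bmask)
}
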