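#' Dyadic frequency band edges for a wavelet scale
#'
#' Returns the band edges used to label wavelet scales. Following the
#' source convention for TR-sampled BOLD data, the printed (nominal) band of
#' scale `j` is indexed from the sampling rate `fs = 1/tr`:
#' `[fs/2^j, fs/2^(j-1)]` for `j < J`, and `[0, fs/2^(J-1)]` for the final
#' scale. Under this convention the scale-1 band lies above the Nyquist
#' frequency; the physical passband of the underlying wavelet detail level
#' is one octave lower, `[fs/2^(j+1), fs/2^j]`, and is reported alongside.
#'
#' @param scaleIndex integer scale in `1..nScales`.
#' @param trSeconds sampling interval in seconds.
#' @param nScales total number of scales `J` (the final scale is the
#'   approximation band reaching down to 0 Hz).
#'
#' @return A list with `scale`, nominal `fLo`, `fHi` (Hz), and physical
#'   passband `fLoPass`, `fHiPass` (Hz).
#'
#' @examples
#' scaleBandEdges(5, 0.72)   # nominal 0.043-0.087 Hz
#' scaleBandEdges(1, 1.0)    # nominal 0.5-1 Hz (above Nyquist)
#'
#' @export
scaleBandEdges <- function(scaleIndex, trSeconds, nScales = 11L) {
  if (length(scaleIndex) != 1L || is.na(scaleIndex) ||
      scaleIndex != round(scaleIndex) ||
      scaleIndex < 1L || scaleIndex > nScales)
    stop("'scaleIndex' must be an integer in 1..", nScales)
  fs <- 1 / trSeconds
  j <- as.integer(scaleIndex)
  if (j < nScales) {
    list(scale = j, fLo = fs / 2^j, fHi = fs / 2^(j - 1L),
         fLoPass = fs / 2^(j + 1L), fHiPass = fs / 2^j)
  } else {
    # approximation band: nominal and physical both reach 0
    list(scale = j, fLo = 0, fHi = fs / 2^(j - 1L),
         fLoPass = 0, fHiPass = fs / 2^j)
  }
}

#' Band metadata table for all scales
#'
#' @inheritParams scaleBandEdges
#' @return data.frame with one row per scale: nominal edges `fLo`/`fHi`,
#'   physical passband `fLoPass`/`fHiPass` (Hz), and a `flagged` column
#'   marking the nominal above-Nyquist band (scale 1) and the very slow
#'   bands (scale 9 and beyond for a 15-min acquisition); these are computed
#'   and retained for completeness.
#' @export
scaleBandTable <- function(nScales, trSeconds) {
  rows <- lapply(seq_len(nScales), scaleBandEdges, trSeconds = trSeconds,
                 nScales = nScales)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$flagged <- out$scale == 1L | out$scale >= 9L
  out
}

#' Maximum decomposition depth for a series length
#'
#' The undecimated (maximal-overlap) transform imposes no dyadic length
#' requirement, but detail levels deeper than `floor(log2(n))` are not
#' resolved; the supported number of scales is `floor(log2(n)) + 1` (detail
#' levels `1..floor(log2(n))` plus the final approximation band).
#'
#' @param nTimepoints series length.
#' @return integer maximum number of scales.
#' @examples
#' maxScales(1200)  # 11
#' @export
maxScales <- function(nTimepoints) {
  as.integer(floor(log2(nTimepoints)) + 1)
}

#' Maximal-overlap wavelet packet decomposition to analytic coefficients
#'
#' Runs the undecimated (maximal-overlap) wavelet transform pyramid twice,
#' once with each real filter bank of an approximate Hilbert wavelet pair,
#' and combines the per-scale outputs as complex analytic coefficients
#' (h-bank real part, g-bank imaginary part). At each level the occupied
#' low-frequency node of the packet tree is split; with this routing the
#' natural output order is already frequency-ordered, so no Gray-code
#' permutation is required. Scales `1..nScales-1` carry the detail bands and
#' scale `nScales` the final approximation band.
#'
#' Boundary handling is circular (periodic), the standard convention for the
#' maximal-overlap transform; the first `(2^j - 1)(L - 1)` coefficients at
#' level `j` (filter length `L`) are boundary-affected and are flagged, not
#' trimmed.
#'
#' @param series numeric vector.
#' @param filters an [HwpFilterPair-class] from [designHwpFilters()].
#' @param nScales number of scales; must not exceed
#'   [maxScales()]`(length(series))`.
#'
#' @return A list with `analytic` (list of complex vectors, one per scale,
#'   each the length of the input), `boundary` (list of logical vectors
#'   flagging boundary-affected coefficients), and `nScales`.
#'
#' @examples
#' fp <- designHwpFilters(2)
#' x <- sin(2 * pi * 0.06 * 0.72 * seq_len(256))
#' w <- modwtPacketDecompose(x, fp, 5)
#' lengths(w$analytic)
#'
#' @export
modwtPacketDecompose <- function(series, filters, nScales) {
  n <- length(series)
  if (nScales < 1L || nScales > maxScales(n))
    stop("'nScales' must be in 1..", maxScales(n),
         " for a series of length ", n)
  x <- matrix(as.numeric(series), ncol = 1L)
  dh <- modwtForward(x, filters@scalingH, filters@h, nScales - 1L)
  dg <- modwtForward(x, filters@scalingG, filters@g, nScales - 1L)
  analytic <- vector("list", nScales)
  for (j in seq_len(nScales - 1L))
    analytic[[j]] <- complex(real = dh$details[[j]][, 1L],
                             imaginary = dg$details[[j]][, 1L])
  analytic[[nScales]] <- complex(real = dh$smooth[, 1L],
                                 imaginary = dg$smooth[, 1L])
  list(analytic = analytic,
       boundary = boundaryFlags(n, nScales, length(filters@h)),
       nScales = nScales)
}

# Boundary-affected coefficient flags per scale (circular convolution).
boundaryFlags <- function(n, nScales, filterLength) {
  lapply(seq_len(nScales), function(j) {
    lev <- min(j, nScales - 1L)
    nb <- min(n, (2^lev - 1L) * (filterLength - 1L))
    seq_len(n) <= nb
  })
}

# Undecimated pyramid for one real filter bank, circular convolution via
# FFT; x is an n x m matrix of m series filtered simultaneously. Filters
# are rescaled by 1/sqrt(2) per level as usual for the maximal-overlap
# transform, which preserves energy:
#   sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2.
modwtForward <- function(x, scaling, wavelet, nLevels) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- wavelet / sqrt(2)
  g <- scaling / sqrt(2)
  V <- stats::mvfft(x)
  details <- vector("list", nLevels)
  for (j in seq_len(nLevels)) {
    Hf <- filterDFT(h, n, 2L^(j - 1L))
    Gf <- filterDFT(g, n, 2L^(j - 1L))
    details[[j]] <- Re(stats::mvfft(V * Hf, inverse = TRUE)) / n
    V <- V * Gf
  }
  list(details = details, smooth = Re(stats::mvfft(V, inverse = TRUE)) / n,
       nLevels = nLevels)
}

# Inverse of modwtForward (single series or matrix); used for the
# perfect-reconstruction checks and band-limited reconstructions.
modwtInverse <- function(decomp, scaling, wavelet) {
  smooth <- as.matrix(decomp$smooth)
  n <- nrow(smooth)
  h <- wavelet / sqrt(2)
  g <- scaling / sqrt(2)
  V <- stats::mvfft(smooth)
  for (j in rev(seq_len(decomp$nLevels))) {
    Hf <- filterDFT(h, n, 2L^(j - 1L))
    Gf <- filterDFT(g, n, 2L^(j - 1L))
    V <- Conj(Gf) * V + Conj(Hf) * stats::mvfft(as.matrix(decomp$details[[j]]))
  }
  out <- Re(stats::mvfft(V, inverse = TRUE)) / n
  if (ncol(out) == 1L) out[, 1L] else out
}

# DFT of a filter upsampled by 'up' (2^(j-1)-1 zeros between taps) on an
# n-point frequency grid, i.e. the level-j transfer function of one
# undecimated pyramid stage. Handles upsampled lengths beyond n (wrap).
filterDFT <- function(f, n, up) {
  idx <- (seq_along(f) - 1L) * up
  om <- 2 * pi * (0:(n - 1L)) / n
  as.vector(exp(-1i * outer(om, idx)) %*% f)
}
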