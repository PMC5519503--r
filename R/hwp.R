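#' Design an approximate Hilbert wavelet pair
#'
#' Constructs two orthonormal wavelet filter banks whose wavelets form an
#' approximate Hilbert transform pair, by the common-factor method: both
#' scaling filters share a spectral factor `Q(z)` and `K` zeros at the
#' Nyquist frequency, and differ by a degree-`L` maximally flat (Thiran)
#' polynomial versus its time reverse, whose all-pass ratio approximates a
#' half-sample delay. The half-sample delay between the two scaling filters
#' makes the combined complex wavelet `psi_h + i psi_g` approximately
#' analytic, which is what yields a meaningful band-limited instantaneous
#' phase from real-valued wavelet coefficients.
#'
#' The spectral factor is obtained by solving the orthonormality (halfband)
#' conditions as a linear system in the autocorrelation coefficients and
#' factoring the result into its minimum-phase root. Both banks are
#' orthonormal to machine precision and have identical magnitude responses
#' by construction (the delay factor is all-pass).
#'
#' @param designOrder integer in `1:4`, selecting the (vanishing moments,
#'   delay-polynomial degree) combination: 1 = (2, 1), 2 = (3, 1),
#'   3 = (3, 2), 4 = (4, 2). Higher orders give longer filters and a more
#'   analytic pair.
#'
#' @return An [HwpFilterPair-class]. The `quality` slot reports the fraction
#'   of energy of the combined complex wavelet (level-5 cascade
#'   approximation) at negative frequencies.
#'
#' @examples
#' fp <- designHwpFilters(2)
#' fp
#' sum(hwpFilters(fp)$scalingH)  # sqrt(2)
#'
#' @export
designHwpFilters <- function(designOrder = 2L) {
  orders <- list(`1` = c(2L, 1L), `2` = c(3L, 1L), `3` = c(3L, 2L),
                 `4` = c(4L, 2L))
  key <- as.character(designOrder)
  if (length(designOrder) != 1L || is.na(designOrder) ||
      !key %in% names(orders))
    stop("unsupported 'designOrder'; supported orders: ",
         paste(names(orders), collapse = ", "))
  kl <- orders[[key]]
  K <- kl[1L]; L <- kl[2L]

  d <- thiranHalfDelay(L)
  bk <- choose(K, 0:K)                    # (1 + z^-1)^K
  a <- convSeq(d, bk)                     # common factor times delay branch
  B <- convSeq(a, rev(a))                 # A(z) A(1/z), symmetric

  # Solve halfband conditions P(z) + P(-z) = 2 for S(z) = Q(z) Q(1/z):
  # p_0 = 1 and p_{2m} = 0, m = 1..M, with P = S * B and M = K + L.
  M <- K + L
  Bget <- function(j) if (abs(j) <= M) B[j + M + 1L] else 0
  Amat <- matrix(0, M + 1L, M + 1L)
  for (row in 0:M) {
    for (i in (-M):M) {
      Amat[row + 1L, abs(i) + 1L] <- Amat[row + 1L, abs(i) + 1L] +
        Bget(2L * row - i)
    }
  }
  s <- solve(Amat, c(1, rep(0, M)))
  S <- c(rev(s[-1L]), s)                  # Laurent coefficients, -M..M

  # Minimum-phase spectral factorization of S.
  rts <- polyroot(S)
  inside <- rts[Mod(rts) < 1]
  if (length(inside) != M)
    stop("spectral factorization failed for design order ", designOrder)
  q <- Re(polyFromRoots(inside))
  t0 <- convSeq(q, rev(q))
  q <- q * sqrt(S[M + 1L] / t0[M + 1L])

  h0 <- convSeq(q, a)                     # scaling filter, bank h
  g0 <- convSeq(q, convSeq(rev(d), bk))   # scaling filter, bank g
  if (sum(h0) < 0) { h0 <- -h0; g0 <- -g0 }
  # The halfband solve forces the final coefficient to zero (even effective
  # length); trim it so downstream filter lengths are exact.
  if (abs(h0[length(h0)]) < 1e-12 && abs(g0[length(g0)]) < 1e-12) {
    h0 <- h0[-length(h0)]
    g0 <- g0[-length(g0)]
  }
  n <- length(h0)
  h1 <- rev(h0) * (-1)^(0:(n - 1L))       # QMF wavelet filters
  g1 <- rev(g0) * (-1)^(0:(n - 1L))

  new("HwpFilterPair", h = h1, g = g1, scalingH = h0, scalingG = g0,
      designOrder = as.integer(designOrder),
      quality = negativeFrequencyEnergy(h0, h1, g0, g1, level = 5L))
}

# Maximally flat (Thiran) polynomial of degree L whose all-pass ratio
# rev(d)/d approximates a half-sample delay.
thiranHalfDelay <- function(L) {
  tau <- 0.5
  vapply(0:L, function(k) {
    (-1)^k * choose(L, k) *
      prod(tau - L + 0:L) / prod(tau - L + k + 0:L)
  }, numeric(1))
}

# Plain polynomial product of two coefficient sequences.
convSeq <- function(x, y) {
  n <- length(x) + length(y) - 1L
  Re(fft(fft(c(x, rep(0, n - length(x)))) *
         fft(c(y, rep(0, n - length(y)))), inverse = TRUE)) / n
}

polyFromRoots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Fraction of energy of the combined complex wavelet at negative
# frequencies, from the level-J equivalent wavelet filter of each bank.
negativeFrequencyEnergy <- function(h0, h1, g0, g1, level = 5L) {
  up <- function(x, m) {
    y <- numeric(length(x) * m)
    y[seq(1L, length(y), by = m)] <- x
    y
  }
  eqh <- up(h1, 2L^(level - 1L))
  eqg <- up(g1, 2L^(level - 1L))
  for (m in 0:(level - 2L)) {
    eqh <- convSeq(eqh, up(h0, 2L^m))
    eqg <- convSeq(eqg, up(g0, 2L^m))
  }
  cf <- eqh + 1i * eqg
  nf <- 2L^(ceiling(log2(length(cf))) + 1L)
  Fc <- fft(c(cf, rep(0, nf - length(cf))))
  neg <- (nf %/% 2L + 2L):nf
  sum(Mod(Fc[neg])^2) / sum(Mod(Fc)^2)
}
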