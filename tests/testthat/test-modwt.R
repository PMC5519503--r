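# Wavelet transform: band arithmetic, perfect reconstruction, energy
# partition, linearity, tone localization.

test_that("nominal band edges follow the dyadic sampling-rate convention", {
  b <- scaleBandEdges(5, 0.72)
  expect_equal(b$fLo, 1 / 0.72 / 32)
  expect_equal(b$fHi, 1 / 0.72 / 16)

  b1 <- scaleBandEdges(1, 1.0)
  expect_equal(b1$fLo, 0.5)
  expect_equal(b1$fHi, 1.0)

  # final scale reaches down to 0 Hz
  bJ <- scaleBandEdges(11, 0.72, nScales = 11)
  expect_identical(bJ$fLo, 0)

  expect_error(scaleBandEdges(0, 0.72), "scaleIndex")
  expect_error(scaleBandEdges(12, 0.72, nScales = 11), "scaleIndex")
})

test_that("bands tile the interval up to the sampling rate", {
  tab <- scaleBandTable(11, 0.72)
  # adjacent nominal bands share an edge: fHi(j+1) == fLo(j)
  for (j in 1:10) expect_equal(tab$fHi[j + 1], tab$fLo[j])
  expect_equal(tab$fHi[1], 1 / 0.72)
  expect_identical(tab$fLo[11], 0)
  # physical passbands sit one octave below nominal labels
  expect_equal(tab$fLoPass[1:10], tab$fLo[1:10] / 2)
  expect_true(all(tab$flagged[c(1, 9:11)]))
})

test_that("maximum depth matches series length", {
  expect_identical(maxScales(1200), 11L)
  expect_identical(maxScales(256), 9L)
  expect_error(modwtPacketDecompose(rnorm(128), defaultFilters, 9),
               "nScales")
})

test_that("decomposition of a zero series is identically zero", {
  w <- modwtPacketDecompose(rep(0, 256), defaultFilters, 6)
  for (z in w$analytic) expect_true(all(Mod(z) == 0))
})

test_that("each real filter bank reconstructs perfectly", {
  set.seed(3)
  x <- rnorm(300)  # deliberately non-dyadic length
  f <- hwpFilters(defaultFilters)
  for (bank in list(c("scalingH", "h"), c("scalingG", "g"))) {
    d <- phasefc:::modwtForward(matrix(x), f[[bank[1]]], f[[bank[2]]], 6)
    xr <- phasefc:::modwtInverse(d, f[[bank[1]]], f[[bank[2]]])
    expect_lt(max(abs(xr - x)), 1e-8)
  }
})

test_that("white-noise energy is partitioned across scales", {
  set.seed(4)
  x <- rnorm(1200)
  w <- modwtPacketDecompose(x, defaultFilters, 11)
  # each bank separately preserves energy; the analytic modulus combines
  # both, so halve it
  en <- sum(vapply(w$analytic, function(z) sum(Mod(z)^2), numeric(1))) / 2
  expect_lt(abs(en / sum(x^2) - 1), 0.05)
})

test_that("the transform is linear", {
  set.seed(5)
  x <- rnorm(256); y <- rnorm(256)
  wx <- modwtPacketDecompose(x, defaultFilters, 5)
  wy <- modwtPacketDecompose(y, defaultFilters, 5)
  wxy <- modwtPacketDecompose(2 * x - 3 * y, defaultFilters, 5)
  for (j in 1:5)
    expect_lt(max(Mod(wxy$analytic[[j]] -
                      (2 * wx$analytic[[j]] - 3 * wy$analytic[[j]]))),
              1e-10)
})

test_that("pure tones localize to the scale whose passband contains them", {
  # FFT oracle: the scale whose physical passband holds the tone frequency
  tr <- 0.72
  n <- 2048
  tab <- scaleBandTable(11, tr)
  for (j in 2:8) {
    f0 <- sqrt(tab$fLoPass[j] * tab$fHiPass[j])  # band geometric center
    x <- sin(2 * pi * f0 * tr * seq_len(n))
    w <- modwtPacketDecompose(x, defaultFilters, 11)
    e <- vapply(w$analytic, function(z) sum(Mod(z)^2), numeric(1))
    expect_identical(which.max(e), j)
  }
})

test_that("boundary flags widen with scale", {
  w <- modwtPacketDecompose(rnorm(512), defaultFilters, 8)
  nb <- vapply(w$boundary, sum, integer(1))
  expect_true(all(diff(nb) >= 0))
  expect_lt(nb[1], 512)
})
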