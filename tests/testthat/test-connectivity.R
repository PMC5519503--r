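# Pairwise Kuramoto synchrony and static/dynamic connectivity.

test_that("closed forms of the pairwise order parameter", {
  th <- runif(16, -pi, pi)
  expect_equal(pairwiseKuramoto(th, th), rep(1, 16))
  expect_equal(pairwiseKuramoto(th, th + pi), rep(0, 16))
  expect_equal(pairwiseKuramoto(th, th + pi / 2),
               rep(sqrt(2) / 2, 16))
  expect_error(pairwiseKuramoto(1:3, 1:4), "lengths differ")
  expect_error(pairwiseKuramoto(c(0, NA), c(0, 0)), "finite")
})

test_that("synchrony depends only on the phase difference", {
  set.seed(10)
  for (rep in 1:20) {
    a <- runif(50, -pi, pi)
    b <- runif(50, -pi, pi)
    cst <- runif(1, -10, 10)
    expect_equal(pairwiseKuramoto(a, b), pairwiseKuramoto(a + cst, b + cst))
  }
})

test_that("dynamicFC equals the brute-force pair/timepoint loop", {
  set.seed(11)
  nr <- 5; nt <- 12
  ph <- array(runif(2 * nr * nt, -pi, pi), c(2, nr, nt))
  mp <- new("MultiscalePhase", phases = ph,
            bands = scaleBandTable(2, 0.72), decimationFactor = 1L,
            trSeconds = 0.72, regionIds = seq_len(nr),
            boundaryMask = matrix(FALSE, 2, nt))
  for (s in 1:2) {
    sync <- dynamicFC(mp, s)
    oracle <- bruteSyncArray(ph[s, , ])
    expect_lt(max(abs(syncValues(sync) - oracle)), 1e-12)
  }
})

test_that("identical and antiphase rows give degenerate synchrony", {
  nt <- 20
  base <- runif(nt, -pi, pi)
  ph <- array(0, c(1, 3, nt))
  ph[1, 1, ] <- base
  ph[1, 2, ] <- base
  ph[1, 3, ] <- atan2(sin(base + pi), cos(base + pi))
  mp <- new("MultiscalePhase", phases = ph,
            bands = scaleBandTable(1, 0.72), decimationFactor = 1L,
            trSeconds = 0.72, regionIds = 1:3,
            boundaryMask = matrix(FALSE, 1, nt))
  r <- syncValues(dynamicFC(mp, 1))
  expect_equal(r[1, 2, ], rep(1, nt))
  expect_lt(max(r[1, 3, ]), 1e-7)
  expect_equal(r[2, 2, ], rep(1, nt))  # diagonal
})

test_that("staticFC is the temporal mean with unit diagonal", {
  set.seed(12)
  r <- array(runif(4 * 4 * 10), c(4, 4, 10))
  for (t in 1:10) {
    r[, , t] <- (r[, , t] + t(r[, , t])) / 2
    diag(r[, , t]) <- 1
  }
  sync <- new("SyncSeries", r = r, scaleIndex = 1L, regionIds = 1:4)
  fc <- staticFC(sync)
  expect_equal(fcMatrix(fc), apply(r, c(1, 2), mean))
  expect_identical(diag(fcMatrix(fc)), rep(1, 4))
  # time-constant series: mean equals any slice
  r2 <- r
  for (t in 1:10) r2[, , t] <- r[, , 1]
  fc2 <- staticFC(new("SyncSeries", r = r2, scaleIndex = 1L,
                      regionIds = 1:4))
  expect_equal(fcMatrix(fc2), r[, , 1])
})

test_that("staticFC commutes with region permutation", {
  set.seed(13)
  nr <- 6; nt <- 30
  ph <- array(runif(nr * nt, -pi, pi), c(1, nr, nt))
  mk <- function(p) new("MultiscalePhase", phases = p,
                        bands = scaleBandTable(1, 0.72),
                        decimationFactor = 1L, trSeconds = 0.72,
                        regionIds = seq_len(nr),
                        boundaryMask = matrix(FALSE, 1, nt))
  perm <- sample(nr)
  fc <- fcMatrix(staticFC(mk(ph), scaleIndex = 1))
  fcp <- fcMatrix(staticFC(mk(ph[, perm, , drop = FALSE]), scaleIndex = 1))
  expect_equal(fcp, fc[perm, perm])
})

test_that("independent uniform phases average to the 2/pi chance floor", {
  set.seed(14)
  nt <- 20000
  r <- pairwiseKuramoto(runif(nt, -pi, pi), runif(nt, -pi, pi))
  expect_lt(abs(mean(r) - 2 / pi), 0.02)
})
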