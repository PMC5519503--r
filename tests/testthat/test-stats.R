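# Repeated-measures GLM, sphericity machinery, post-hoc correlations.

test_that("degrees of freedom reproduce the regions-minus-covariates rule", {
  set.seed(40)
  Y <- matrix(rnorm(82 * 11), 82)
  pet1 <- regionalPetVector(runif(82, 1, 3), "rCPS")
  pet2 <- regionalPetVector(runif(82, 3, 7), "SUV")
  a1 <- assocEffects(rmGlm(Y, pet1))
  expect_identical(a1$df2[1], 80)           # one covariate
  a2 <- assocEffects(rmGlm(Y, list(pet1, pet2)))
  expect_identical(a2$df2[1:2], c(79, 79))  # two covariates
  expect_identical(a2$df1[1:2], c(1, 1))
})

test_that("within-unit F, Mauchly and GG match the stats-package oracles", {
  set.seed(41)
  n <- 40; k <- 6
  x <- rnorm(n)
  Y <- matrix(rnorm(n * k), n) + outer(rnorm(n), rep(1, k)) +
    outer(x, seq(0, 1, length.out = k))
  res <- rmGlm(Y, x)
  eff <- assocEffects(res)

  mod <- stats::lm(Y ~ scale(x))
  or <- stats::anova(mod, X = ~1, test = "Spherical")
  expect_equal(eff$F[eff$effect == "covariate x scale"],
               or["scale(x)", "F"], tolerance = 1e-10)
  mt <- stats::mauchly.test(mod, X = ~1)
  expect_equal(assocMauchlyW(res), unname(mt$statistic), tolerance = 1e-10)
  expect_equal(res@mauchlyP, mt$p.value, tolerance = 1e-3)

  # main effect agrees with the scale-averaged regression
  lmain <- stats::summary.lm(stats::lm(rowMeans(Y) ~ scale(x)))
  expect_equal(eff$F[1], lmain$coefficients[2, "t value"]^2,
               tolerance = 1e-10)
})

test_that("two within levels collapse the sphericity machinery", {
  set.seed(42)
  Y <- matrix(rnorm(50 * 2), 50)
  expect_identical(ggEpsilon(Y), 1)
  m <- mauchlySphericity(Y)
  expect_identical(m$W, 1)
})

test_that("epsilon attains its lower bound on rank-one contrast structure", {
  set.seed(43)
  n <- 60; k <- 5
  a <- rnorm(n); cst <- rnorm(n)
  Y <- outer(a, seq(-1, 1, length.out = k)) + outer(cst, rep(1, k))
  expect_equal(ggEpsilon(Y), 1 / (k - 1), tolerance = 1e-10)
})

test_that("epsilon is near one under a spherical covariance", {
  set.seed(44)
  Y <- matrix(rnorm(600 * 6), 600)  # iid: compound symmetry holds
  expect_gt(ggEpsilon(Y), 0.95)
  expect_gt(mauchlySphericity(Y)$p, 0.01)
})

test_that("strong AR(1) scale correlation is detected as non-spherical", {
  set.seed(45)
  k <- 11; n <- 82; rho <- 0.9
  rejections <- 0L
  for (rep in 1:30) {
    e <- matrix(rnorm(n * k), n)
    for (j in 2:k) e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * e[, j]
    if (mauchlySphericity(e)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 29L)
})

test_that("a perfectly scale-constant covariate effect is detected cleanly", {
  x <- seq(1, 3, length.out = 82)
  Y <- matrix(rep(2 + 1.5 * x, 11), ncol = 11)   # no noise at all
  res <- rmGlm(Y, x)
  eff <- assocEffects(res)
  expect_lt(eff$p[1], 1e-12)
  expect_identical(eff$F[eff$effect == "covariate x scale"], 0)
})

test_that("identical covariates are rejected as collinear", {
  Y <- matrix(rnorm(82 * 4), 82)
  x <- runif(82, 1, 2)
  expect_error(rmGlm(Y, list(regionalPetVector(x, "rCPS"),
                             regionalPetVector(x, "SUV"))),
               "collinear")
})

test_that("partial correlation reduces to the plain one when controls are
           orthogonal", {
  set.seed(46)
  n <- 4000
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  z <- rnorm(n)  # independent of both
  plain <- posthocCorrelations(matrix(y), x)
  part <- posthocCorrelations(matrix(y), x, control = z)
  expect_equal(part$r, plain$r, tolerance = 0.03)
  expect_equal(plain$r, 0.5, tolerance = 0.05)
})

test_that("an exact relationship is significant at any corrected level", {
  x <- runif(82, 1, 2)
  res <- posthocCorrelations(matrix(x), x, familySize = 44)
  expect_equal(res$r, 1)
  expect_true(res$significant)
})

test_that("partial correlation recovers a known population value", {
  set.seed(47)
  n <- 100000
  # construct (y, x, z) with known partial correlation r_yx.z = 0.3
  z <- rnorm(n)
  ex <- rnorm(n)
  x <- 0.5 * z + sqrt(0.75) * ex
  # y = a z + (residual part): conditional on z, corr(y, x | z) = b
  b <- 0.3
  y <- 0.4 * z + sqrt(0.84) * (b * ex + sqrt(1 - b^2) * rnorm(n))
  res <- posthocCorrelations(matrix(y), x, control = z)
  expect_equal(res$r, 0.3, tolerance = 0.01)
})

test_that("degenerate controls are rejected", {
  x <- rnorm(50)
  expect_error(posthocCorrelations(matrix(x + 0.1), x, control = x),
               "degenerate")
})

test_that("partial r is invariant to affine rescaling", {
  set.seed(48)
  y <- rnorm(60); x <- rnorm(60); z <- rnorm(60)
  r0 <- posthocCorrelations(matrix(y), x, control = z)$r
  r1 <- posthocCorrelations(matrix(3 * y - 2), 10 * x + 5,
                            control = -4 * z + 1)$r
  expect_equal(abs(r1), abs(r0), tolerance = 1e-12)
})

test_that("Bonferroni keeps the family-wise error controlled under the null", {
  set.seed(49)
  fwer <- 0L
  nrep <- 200
  for (rep in seq_len(nrep)) {
    Y <- matrix(rnorm(82 * 11), 82)
    x <- rnorm(82)
    res <- posthocCorrelations(Y, x, familySize = 44)
    if (any(res$significant)) fwer <- fwer + 1L
  }
  # 11 of 44 family members tested per replicate -> expected FWER well
  # below alpha; allow binomial slack around 0.05 * 11/44
  expect_lt(fwer / nrep, 0.05)
})
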