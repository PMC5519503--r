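# Temporal coefficient of variation and subject averaging.

test_that("CV of canonical series", {
  expect_identical(temporalCV(c(2, 2, 2, 2)), 0)
  # population convention: sd([1,3]) = 1, mean 2
  expect_equal(temporalCV(c(1, 3)), 0.5)
  expect_error(temporalCV(3), "at least 2")
})

test_that("CV is invariant to positive rescaling", {
  set.seed(30)
  for (rep in 1:10) {
    x <- runif(50, 0.5, 2)
    a <- runif(1, 0.01, 100)
    expect_equal(temporalCV(a * x), temporalCV(x))
  }
})

test_that("a degenerate mean yields a flagged missing CV", {
  expect_true(is.na(temporalCV(c(1e-15, -1e-15, 0))))
})

test_that("stabilityTable collapses a dynamic table and honours boundaries", {
  set.seed(31)
  nt <- 40
  r <- array(runif(3 * 3 * nt, 0.2, 1), c(3, 3, nt))
  for (t in seq_len(nt)) {
    r[, , t] <- (r[, , t] + t(r[, , t])) / 2
    diag(r[, , t]) <- 1
  }
  sync <- new("SyncSeries", r = r, scaleIndex = 2L, regionIds = 1:3)
  dyn <- computeMetricTable(sync, 0, metrics = "node_strength")
  st <- stabilityTable(dyn)
  # oracle: CV of the per-timepoint row sums
  for (i in 1:3) {
    series <- vapply(seq_len(nt), function(t) {
      W <- r[, , t]; diag(W) <- 0; sum(W[i, ])
    }, numeric(1))
    expect_equal(st$cv[st$region == i], temporalCV(series))
  }
  # boundary exclusion drops the flagged timepoints
  bnd <- seq_len(nt) <= 10
  st2 <- stabilityTable(dyn, boundary = bnd)
  expect_identical(unique(st2$nTimepointsUsed), 30L)
  series <- vapply(11:nt, function(t) {
    W <- r[, , t]; diag(W) <- 0; sum(W[1, ])
  }, numeric(1))
  expect_equal(st2$cv[st2$region == 1], temporalCV(series))
})

test_that("subject averaging is the elementwise mean with NA handling", {
  tab <- data.frame(region = rep(1:3, 2), scale = 1,
                    metric = rep(c("node_strength", "local_efficiency"),
                                 each = 3),
                    value = runif(6))
  expect_equal(subjectAverage(list(tab))$value, tab$value)
  tab3 <- tab; tab3$value <- 3 * tab$value
  expect_equal(subjectAverage(list(tab, tab3))$value, 2 * tab$value)

  set.seed(32)
  tabs <- lapply(1:5, function(i) { t <- tab; t$value <- rnorm(6); t })
  avg <- subjectAverage(tabs)
  oracle <- rowMeans(vapply(tabs, `[[`, numeric(6), "value"))
  expect_equal(avg$value, oracle)

  # missing values are dropped with a count
  tabs[[2]]$value[4] <- NA
  avg2 <- subjectAverage(tabs)
  expect_identical(avg2$nSubjects[4], 4L)
  expect_equal(avg2$value[4],
               mean(vapply(tabs, `[[`, numeric(6), "value")[4, ],
                    na.rm = TRUE))

  bad <- tab[tab$region != 3, ]
  expect_error(subjectAverage(list(tab, bad)), "mismatched")
})

test_that("strongly coupled hubs are more stable than the periphery", {
  # compact simulated regime: persistent hubs keep higher, steadier
  # synchrony, so their strength CV falls below the non-hub median
  spec <- simulationSpec(nRegions = 40, nTimepoints = 600,
                        hubIds = 1:3, seed = 77)
  roi <- simulateCoupledBold(spec)
  mp <- multiscalePhase(roi, defaultFilters, nScales = 8)
  sync <- dynamicFC(mp, scaleIndex = 4)
  dyn <- computeMetricTable(sync, 0, metrics = "node_strength")
  st <- stabilityTable(dyn, boundary = boundaryMask(mp)[4, ])
  stat <- metricByScale(
    computeMetricTable(staticFC(sync), 0, metrics = "node_strength"),
    "node_strength")[, 1]
  cv <- st$cv[order(st$region)]
  expect_true(all(cv[1:3] < stats::median(cv[-(1:3)])))
  # and across regions, higher mean strength goes with lower CV
  expect_lt(stats::cor(stat, cv), 0)
})
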