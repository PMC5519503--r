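# Small shared fixtures, generated in code at test time.

quickRoi <- function(nRegions = 6, nTimepoints = 256, tr = 0.72,
                     seed = 101) {
  set.seed(seed)
  roiTimeSeries(matrix(rnorm(nRegions * nTimepoints), nRegions),
                trSeconds = tr)
}

# Two 4-node cliques (intra-weight ~0.9) joined by a single weak bridge.
twoCliqueBridge <- function(intra = 0.9, bridge = 0.1, jitter = 0) {
  W <- matrix(0, 8, 8)
  for (blk in list(1:4, 5:8))
    for (i in blk) for (j in blk) if (i < j) W[i, j] <- W[j, i] <- intra
  W[4, 5] <- W[5, 4] <- bridge
  if (jitter > 0) {
    up <- upper.tri(W) & W > 0
    W[up] <- W[up] + stats::runif(sum(up), 0, jitter)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
  }
  W
}

defaultFilters <- designHwpFilters(2L)
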