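# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package implementation.

# Per-voxel loop mean of a 4D image over an atlas label.
voxelLoopRoiMeans <- function(bold, atlas, labels) {
  nt <- dim(bold)[4]
  out <- matrix(NA_real_, length(labels), nt)
  for (li in seq_along(labels)) {
    idx <- which(atlas == labels[li], arr.ind = TRUE)
    for (t in seq_len(nt)) {
      acc <- 0
      for (v in seq_len(nrow(idx)))
        acc <- acc + bold[idx[v, 1], idx[v, 2], idx[v, 3], t]
      out[li, t] <- acc / nrow(idx)
    }
  }
  out
}

voxelLoopPetMeans <- function(pet, atlas, labels) {
  vapply(labels, function(l) {
    idx <- which(atlas == l, arr.ind = TRUE)
    acc <- 0
    for (v in seq_len(nrow(idx)))
      acc <- acc + pet[idx[v, 1], idx[v, 2], idx[v, 3]]
    acc / nrow(idx)
  }, numeric(1))
}

# All-pairs shortest path lengths by Floyd-Warshall on 1/weight lengths.
floydWarshall <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bruteStrength <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i)
    out[i] <- out[i] + W[i, j]
  out
}

# Onnela geometric-mean clustering by explicit triple loop.
bruteClustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- (W / mx)^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + Wh[i, j] * Wh[i, h] * Wh[j, h]
    out[i] <- acc / (k * (k - 1))
  }
  out
}

bruteGlobalEfficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  d <- floydWarshall(W)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) acc <- acc + 1 / d[i, j]
  acc / (n * (n - 1))
}

bruteLocalEfficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- bruteGlobalEfficiency(W[nb, nb, drop = FALSE])
  }
  out
}

# Betweenness by explicit shortest-path counting: sigma_st via dynamic
# programming over distance-ordered predecessors, fractional credit
# sigma_sv * sigma_vt / sigma_st when v lies on a shortest s-t path.
bruteBetweenness <- function(W, tol = 1e-12) {
  n <- nrow(W)
  d <- floydWarshall(W)
  len <- matrix(Inf, n, n)
  len[W > 0] <- 1 / W[W > 0]
  sigma <- matrix(0, n, n)  # number of shortest paths s -> t
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      for (u in seq_len(n)) {
        if (u != t && is.finite(d[s, u]) && is.finite(len[u, t]) &&
            abs(d[s, u] + len[u, t] - d[s, t]) < tol)
          sigma[s, t] <- sigma[s, t] + sigma[s, u]
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (s > t) next  # undirected: count each unordered pair once
      if (is.finite(d[s, t]) && sigma[s, t] > 0 &&
          abs(d[s, v] + d[v, t] - d[s, t]) < tol)
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bc
}

# Random symmetric nonnegative zero-diagonal weight matrix.
randomAdjacency <- function(n, density = 0.5, weighted = TRUE) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  m <- sum(up)
  present <- stats::runif(m) < density
  w <- if (weighted) stats::runif(m, 0.05, 1) else 1
  W[up] <- present * w
  W <- W + t(W)
  W
}

# Brute-force pairwise Kuramoto over pairs and timepoints.
bruteSyncArray <- function(theta) {
  nr <- nrow(theta)
  nt <- ncol(theta)
  r <- array(NA_real_, c(nr, nr, nt))
  for (i in seq_len(nr)) for (j in seq_len(nr)) for (t in seq_len(nt))
    r[i, j, t] <- Mod((exp(1i * theta[i, t]) + exp(1i * theta[j, t])) / 2)
  r
}
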