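#' Cost-efficiency threshold selection
#'
#' Chooses the connection-density (cost) threshold that maximizes the
#' cost-efficiency of the binarized network: for each candidate cost `k`
#' (fraction of possible edges retained), the weight cutoff achieving that
#' cost is found, the graph is binarized, the binary global efficiency
#' `E_glob` (mean inverse shortest path length over pairs) is computed, and
#' the score `E_glob - k` is maximized. Ties break toward the sparser
#' (lower-cost) network.
#'
#' @param fc a [StaticFC-class] or a square symmetric weight matrix.
#' @param costGrid ascending vector of candidate costs in (0, 1); default
#'   `seq(0.05, 0.5, by = 0.01)`.
#' @return A list of class `ThresholdSpec`: `scaleIndex`, `thresholdValue`
#'   (weight cutoff), `costAtThreshold` (achieved cost), `efficiency`,
#'   `costEfficiency`, `provenance`, and the full search `table`.
#' @examples
#' set.seed(1)
#' w <- matrix(runif(64), 8); w <- (w + t(w)) / 2; diag(w) <- 1
#' costEfficiencyThreshold(w)$costAtThreshold
#' @export
costEfficiencyThreshold <- function(fc, costGrid = seq(0.05, 0.5, by = 0.01)) {
  if (length(costGrid) == 0L) stop("'costGrid' must be non-empty")
  if (any(costGrid <= 0) || any(costGrid >= 1) || is.unsorted(costGrid))
    stop("'costGrid' must be ascending within (0, 1)")
  scaleIdx <- NA_integer_
  if (is(fc, "StaticFC")) {
    scaleIdx <- fc@scaleIndex
    fc <- fc@matrix
  }
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  n <- nrow(fc)
  w <- fc[upper.tri(fc)]
  npairs <- length(w)
  ws <- sort(w, decreasing = TRUE)
  tab <- data.frame(cost = costGrid, threshold = NA_real_,
                    achievedCost = NA_real_, efficiency = NA_real_,
                    costEfficiency = NA_real_)
  anyConnected <- FALSE
  for (i in seq_along(costGrid)) {
    m <- max(1L, round(costGrid[i] * npairs))
    thr <- ws[m]
    adj <- (fc >= thr & fc > 0) * 1
    diag(adj) <- 0
    eg <- globalEfficiencyBinary(adj)
    kAch <- sum(adj[upper.tri(adj)]) / npairs
    tab$threshold[i] <- thr
    tab$achievedCost[i] <- kAch
    tab$efficiency[i] <- eg
    tab$costEfficiency[i] <- eg - costGrid[i]
    if (isConnectedBinary(adj)) anyConnected <- TRUE
  }
  if (!anyConnected)
    warning("graph disconnected at every candidate cost; ",
            "returning argmax of cost-efficiency regardless")
  best <- which.max(tab$costEfficiency)  # first max = lowest cost on ties
  structure(list(scaleIndex = scaleIdx,
                 thresholdValue = tab$threshold[best],
                 costAtThreshold = tab$achievedCost[best],
                 efficiency = tab$efficiency[best],
                 costEfficiency = tab$costEfficiency[best],
                 provenance = "per_subject", table = tab),
            class = "ThresholdSpec")
}

#' @export
print.ThresholdSpec <- function(x, ...) {
  cat(sprintf(
    "ThresholdSpec (%s): weight cutoff %.4f, cost %.3f, E_glob %.3f, C-E %.3f\n",
    x$provenance, x$thresholdValue, x$costAtThreshold, x$efficiency,
    x$costEfficiency))
  invisible(x)
}

#' Average thresholds across an independent group
#'
#' Mirrors the group-mean thresholding strategy: cost-efficiency thresholds
#' are estimated in an independent set of subjects and their mean weight
#' cutoff is applied to the analysis cohort.
#'
#' @param specs list of `ThresholdSpec` objects for the same scale.
#' @return A `ThresholdSpec` with `provenance = "group_mean"`.
#' @export
groupMeanThreshold <- function(specs) {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "ThresholdSpec")))
  structure(list(
    scaleIndex = specs[[1L]]$scaleIndex,
    thresholdValue = mean(vapply(specs, `[[`, numeric(1), "thresholdValue")),
    costAtThreshold = mean(vapply(specs, `[[`, numeric(1), "costAtThreshold")),
    efficiency = mean(vapply(specs, `[[`, numeric(1), "efficiency")),
    costEfficiency = mean(vapply(specs, `[[`, numeric(1), "costEfficiency")),
    provenance = "group_mean", table = NULL), class = "ThresholdSpec")
}

#' Apply a weight threshold to a connectivity matrix
#'
#' Weights below the cutoff are set to zero; surviving weights are retained
#' (the graph stays weighted). The diagonal is zeroed: self-loops are
#' excluded from all graph metrics.
#'
#' @param fc a [StaticFC-class], square matrix, or one timepoint of a
#'   synchrony series.
#' @param spec a `ThresholdSpec` or a bare numeric cutoff.
#' @return numeric weighted adjacency matrix.
#' @export
applyThreshold <- function(fc, spec) {
  if (is(fc, "StaticFC")) fc <- fc@matrix
  thr <- if (inherits(spec, "ThresholdSpec")) spec$thresholdValue
         else as.numeric(spec)
  w <- fc
  w[w < thr] <- 0
  diag(w) <- 0
  w
}

#' Node strength
#'
#' Sum of all link weights incident to each node (the weighted degree).
#'
#' @param W nonnegative symmetric weighted adjacency matrix with zero
#'   diagonal.
#' @return numeric vector, one value per node.
#' @export
nodeStrength <- function(W) {
  checkAdjacency(W)
  rowSums(W)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) weighted clustering: with weights
#' max-normalized to `[0, 1]`,
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`
#' where `k_i` is the binary degree; `C_i = 0` for nodes with fewer than two
#' neighbours. On binary graphs this reduces to the textbook
#' triangles-over-triples definition.
#'
#' @inheritParams nodeStrength
#' @return numeric vector in [0, 1].
#' @export
clusteringCoefficient <- function(W) {
  checkAdjacency(W)
  mx <- max(W)
  if (mx == 0) return(numeric(nrow(W)))
  Wn <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  tri <- diag(Wn %*% Wn %*% Wn)     # 2 x weighted triangle count per node
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, tri / denom, 0)
  out
}

#' Weighted local efficiency
#'
#' For each node, the weighted global efficiency of the subgraph induced by
#' its neighbours: the mean inverse shortest weighted path length over all
#' neighbour pairs, with edge lengths `1/weight`. Nodes with fewer than two
#' neighbours score 0; disconnected neighbour pairs contribute 0.
#'
#' @inheritParams nodeStrength
#' @return numeric vector (in [0, 1] for weights in [0, 1]).
#' @export
localEfficiency <- function(W) {
  checkAdjacency(W)
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    out[i] <- globalEfficiencyWeighted(sub)
  }
  out
}

#' Weighted betweenness centrality
#'
#' Number of shortest paths between all node pairs that pass through each
#' node, with edge lengths `1/weight` and fractional credit shared among
#' tied shortest paths. Unnormalized.
#'
#' @inheritParams nodeStrength
#' @return numeric vector >= 0.
#' @export
betweennessCentrality <- function(W) {
  checkAdjacency(W)
  g <- graphFromAdjacency(W)
  if (igraph::ecount(g) == 0L) return(numeric(nrow(W)))
  igraph::betweenness(g, directed = FALSE,
                      weights = 1 / igraph::E(g)$weight)
}

#' Node metric table for static or dynamic connectivity
#'
#' Thresholds the connectivity matrix (or every timepoint of a synchrony
#' series) and computes the four node metrics: clustering coefficient,
#' local efficiency, node strength, betweenness centrality. Timepoints
#' whose thresholded graph has no surviving edge yield zero metrics with a
#' warning.
#'
#' @param x a [StaticFC-class] (static case) or [SyncSeries-class] (dynamic
#'   case).
#' @param spec a `ThresholdSpec` or numeric cutoff; 0 keeps every positive
#'   weight.
#' @param metrics character subset of
#'   `c("clustering_coefficient", "local_efficiency", "node_strength",
#'   "betweenness_centrality")`.
#' @return A long-format data.frame: `region`, `scale`, `metric`, `value`,
#'   plus `timepoint` in the dynamic case.
#' @export
computeMetricTable <- function(x, spec = 0,
                               metrics = c("clustering_coefficient",
                                           "local_efficiency",
                                           "node_strength",
                                           "betweenness_centrality")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is(x, "StaticFC")) {
    W <- applyThreshold(x, spec)
    vals <- metricValues(W, metrics)
    return(data.frame(region = rep(x@regionIds, length(metrics)),
                      scale = x@scaleIndex,
                      metric = rep(metrics, each = nrow(W)),
                      value = unlist(vals, use.names = FALSE)))
  }
  stopifnot(is(x, "SyncSeries"))
  nt <- dim(x@r)[3L]
  nr <- dim(x@r)[1L]
  nEmpty <- 0L
  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    W <- applyThreshold(x@r[, , t], spec)
    if (all(W == 0)) nEmpty <- nEmpty + 1L
    vals <- metricValues(W, metrics)
    rows[[t]] <- data.frame(region = rep(x@regionIds, length(metrics)),
                            scale = x@scaleIndex, timepoint = t,
                            metric = rep(metrics, each = nr),
                            value = unlist(vals, use.names = FALSE))
  }
  if (nEmpty > 0L)
    warning(nEmpty, " timepoint(s) had an empty thresholded graph; ",
            "metrics set to 0 there")
  do.call(rbind, rows)
}

metricValues <- function(W, metrics) {
  lapply(metrics, function(m) {
    switch(m,
      clustering_coefficient = clusteringCoefficient(W),
      local_efficiency = localEfficiency(W),
      node_strength = nodeStrength(W),
      betweenness_centrality = betweennessCentrality(W))
  })
}

checkAdjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("adjacency must be a square matrix")
  if (any(W < 0)) stop("adjacency weights must be nonnegative")
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero")
  if (max(abs(W - t(W))) > 1e-10) stop("adjacency must be symmetric")
  invisible(TRUE)
}

graphFromAdjacency <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Binary global efficiency: mean 1/d over ordered pairs, unreachable -> 0.
globalEfficiencyBinary <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# Weighted global efficiency with edge length 1/weight.
globalEfficiencyWeighted <- function(W) {
  n <- nrow(W)
  if (n < 2L) return(0)
  g <- graphFromAdjacency(W)
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

isConnectedBinary <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}
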