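#' Simulation settings for coupled-oscillator BOLD data
#'
#' Bundles the parameters of the synthetic resting-state generator. The
#' defaults emulate the acquisition the pipeline targets: 82 atlas regions,
#' TR = 0.72 s, 1200 volumes (15 min), oscillations in the 0.04-0.08 Hz
#' band with network-structured phase coupling and a handful of planted hub
#' regions.
#'
#' @param nRegions number of regions (default 82).
#' @param trSeconds sampling interval (default 0.72 s).
#' @param nTimepoints number of emitted volumes (default 1200).
#' @param couplingMatrix nonnegative symmetric zero-diagonal matrix; default
#'   a planted-hub network from [makePlantedHubNetwork()].
#' @param globalCoupling Kuramoto coupling gain `K >= 0` multiplying the
#'   (degree-normalized) coupling term; the default 0.25 puts the default
#'   network in partial synchrony (mean pairwise synchrony about 0.8,
#'   between the 2/pi chance floor and full lock).
#' @param freqBand intrinsic-frequency band in Hz (uniform draw), default
#'   `c(0.04, 0.08)`; must lie below the Nyquist frequency.
#' @param noiseSd standard deviation of additive white observation noise on
#'   the emitted signal (default 0.3, a moderately noisy BOLD observation
#'   of a unit-amplitude oscillation).
#' @param phaseNoiseSd phase diffusion (rad/sqrt(s)) of the Euler-Maruyama
#'   integration, default 0.4; sized so that stochastic phase slips, rather
#'   than the intrinsic-frequency draw, limit pairwise synchrony, which
#'   makes synchrony reflect structural coupling.
#' @param hubIds indices of planted hub regions; default the first 4.
#' @param hubWeightRatio hub-to-base coupling weight ratio used when
#'   building the default network (default 3).
#' @param seed integer seed driving every random element.
#' @return list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nRegions = 82L, trSeconds = 0.72,
                           nTimepoints = 1200L, couplingMatrix = NULL,
                           globalCoupling = 0.25,
                           freqBand = c(0.04, 0.08), noiseSd = 0.3,
                           phaseNoiseSd = 0.4,
                           hubIds = seq_len(4L), hubWeightRatio = 3,
                           seed = 1L) {
  stopifnot(nRegions >= 2L, trSeconds > 0, nTimepoints >= 64L,
            globalCoupling >= 0, noiseSd >= 0, phaseNoiseSd >= 0)
  if (freqBand[1L] <= 0 || freqBand[2L] >= 1 / (2 * trSeconds))
    stop("'freqBand' must lie within (0, Nyquist)")
  if (is.null(couplingMatrix))
    couplingMatrix <- makePlantedHubNetwork(
      nRegions, hubIds = hubIds, baseWeight = 1,
      hubWeight = hubWeightRatio, seed = deriveSeed(seed, 1L))
  stopifnot(nrow(couplingMatrix) == nRegions,
            all(couplingMatrix >= 0),
            all(diag(couplingMatrix) == 0))
  structure(list(nRegions = as.integer(nRegions), trSeconds = trSeconds,
                 nTimepoints = as.integer(nTimepoints),
                 couplingMatrix = couplingMatrix,
                 globalCoupling = globalCoupling, freqBand = freqBand,
                 noiseSd = noiseSd, phaseNoiseSd = phaseNoiseSd,
                 hubIds = as.integer(hubIds), seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat(sprintf(
    "SimulationSpec: %d regions x %d volumes, TR %.3g s, K = %.2g, band %.3g-%.3g Hz, %d hubs\n",
    x$nRegions, x$nTimepoints, x$trSeconds, x$globalCoupling,
    x$freqBand[1], x$freqBand[2], length(x$hubIds)))
  invisible(x)
}

#' Coupling matrix with planted hub regions
#'
#' Symmetric nonnegative all-to-all coupling matrix in which edges incident
#' to designated hub regions are drawn around `hubWeight` and all others
#' around `baseWeight` (independent lognormal jitter, 15% coefficient of
#' variation), giving the hub rows systematically larger sums. Diagonal is
#' zero.
#'
#' @param nRegions number of regions.
#' @param hubIds indices of hub regions.
#' @param baseWeight,hubWeight mean coupling weight for non-hub and
#'   hub-incident edges; `hubWeight > baseWeight` plants hubs.
#' @param seed integer seed.
#' @return `nRegions x nRegions` numeric matrix.
#' @examples
#' W <- makePlantedHubNetwork(20, hubIds = 1:2, baseWeight = 1,
#'                            hubWeight = 3, seed = 1)
#' order(rowSums(W), decreasing = TRUE)[1:2]  # the planted hubs
#' @export
makePlantedHubNetwork <- function(nRegions, hubIds = seq_len(4L),
                                  baseWeight = 1, hubWeight = 3,
                                  seed = 1L) {
  stopifnot(nRegions >= 2L, all(hubIds >= 1L), all(hubIds <= nRegions),
            baseWeight >= 0, hubWeight >= 0)
  withSeed(seed, {
    W <- matrix(0, nRegions, nRegions)
    isHub <- seq_len(nRegions) %in% hubIds
    cv <- 0.15
    sdl <- sqrt(log(1 + cv^2))
    for (i in seq_len(nRegions - 1L)) {
      for (j in (i + 1L):nRegions) {
        mu <- if (isHub[i] || isHub[j]) hubWeight else baseWeight
        w <- if (mu > 0) mu * exp(stats::rnorm(1L, -sdl^2 / 2, sdl)) else 0
        W[i, j] <- W[j, i] <- w
      }
    }
    W
  })
}

#' Simulate coupled-oscillator BOLD time series
#'
#' Euler-Maruyama integration of Kuramoto phase oscillators on the coupling
#' network,
#' `dtheta_i = [omega_i + (K/n) sum_j W_ij sin(theta_j - theta_i)] dt
#'  + sigma dB`,
#' at internal step `dt = TR/10`, emitted as `x_i(t) = sin(theta_i(t))`
#' plus white observation noise, sampled every TR. Intrinsic frequencies
#' `omega_i` are drawn uniformly over `2*pi*freqBand`. No hemodynamic
#' convolution is applied; an optional first-order lowpass is available.
#'
#' @param spec a `SimulationSpec` from [simulationSpec()].
#' @param lowpass optional lowpass time constant in seconds applied to the
#'   emitted signal (default `NULL`, off).
#' @return A [RoiTimeSeries-class].
#' @export
simulateCoupledBold <- function(spec, lowpass = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  n <- spec$nRegions
  W <- spec$couplingMatrix / n
  K <- spec$globalCoupling
  dt <- spec$trSeconds / 10
  maxDeg <- max(rowSums(W))
  if (K * maxDeg * dt > 0.5)
    stop("unstable integration: K * max degree * dt = ",
         signif(K * maxDeg * dt, 3), " > 0.5; reduce dt or K")
  nSteps <- spec$nTimepoints * 10L
  withSeed(deriveSeed(spec$seed, 2L), {
    omega <- 2 * pi * stats::runif(n, spec$freqBand[1L], spec$freqBand[2L])
    theta <- stats::runif(n, -pi, pi)
    sigma <- spec$phaseNoiseSd * sqrt(dt)
    X <- matrix(0, n, spec$nTimepoints)
    col <- 0L
    for (s in seq_len(nSteps)) {
      st <- sin(theta); ct <- cos(theta)
      # sum_j W_ij sin(theta_j - theta_i) via the angle-difference identity
      coupling <- K * (ct * (W %*% st) - st * (W %*% ct))
      theta <- theta + (omega + coupling) * dt + sigma * stats::rnorm(n)
      if (s %% 10L == 0L) {
        col <- col + 1L
        X[, col] <- sin(theta)
      }
    }
    if (!is.null(lowpass)) {
      a <- exp(-spec$trSeconds / lowpass)
      for (t in 2:ncol(X)) X[, t] <- a * X[, t - 1L] + (1 - a) * X[, t]
    }
    X <- X + spec$noiseSd * matrix(stats::rnorm(length(X)), nrow = n)
    roiTimeSeries(X, trSeconds = spec$trSeconds)
  })
}

#' Synthetic PET covariate vectors tied to hubness
#'
#' Generates rCPS and SUV regional vectors by a Gaussian copula so that the
#' rCPS vector correlates with a supplied hubness score (e.g. planted
#' coupling row sums) at about `rhoHub`, and the two tracers correlate with
#' each other at about `rhoBetween` (0.63 being the empirically reported
#' tracer correlation this generator emulates). Latent normals are mapped
#' to positive values on realistic scales (rCPS around 2 nmol/g/min, SUV
#' around 5).
#'
#' @param hubness numeric vector of region hubness scores.
#' @param rhoHub target correlation between rCPS and hubness, |rho| < 1.
#' @param rhoBetween target correlation between rCPS and SUV, |rho| < 1.
#' @param seed integer seed.
#' @return list with elements `rcps` and `suv`, both
#'   [RegionalPetVector-class].
#' @examples
#' pet <- synthPetVectors(rnorm(82), rhoHub = 0.6, rhoBetween = 0.63,
#'                        seed = 1)
#' cor(petValues(pet$rcps), petValues(pet$suv))
#' @export
synthPetVectors <- function(hubness, rhoHub, rhoBetween, seed = 1L) {
  stopifnot(abs(rhoHub) < 1, abs(rhoBetween) < 1)
  n <- length(hubness)
  withSeed(seed, {
    h <- as.numeric(scale(hubness))
    zR <- rhoHub * h + sqrt(1 - rhoHub^2) * stats::rnorm(n)
    zS <- rhoBetween * zR + sqrt(1 - rhoBetween^2) * stats::rnorm(n)
    mk <- function(z, mu, sd) {
      v <- mu + sd * z
      if (any(v <= 0)) v <- v - min(v) + 0.05 * mu  # shift positive
      v
    }
    list(rcps = regionalPetVector(mk(zR, 2, 0.3), "rCPS",
                                  regionIds = seq_len(n)),
         suv = regionalPetVector(mk(zS, 5, 1), "SUV",
                                 regionIds = seq_len(n)))
  })
}
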