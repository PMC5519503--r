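#' Repeated-measures GLM relating network metrics to PET covariates
#'
#' Fits a univariate repeated-measures analysis of covariance with brain
#' regions as units, wavelet scale as the within-unit factor, and one or two
#' regional PET measures as continuous between-unit covariates. For each
#' covariate it reports the main-effect F (test on the scale-averaged
#' metric; denominator df `n - 1 - n_covariates`, reproducing the familiar
#' F(1,80) / F(1,79) pattern at 82 regions) and the covariate-by-scale
#' interaction F from the orthonormal-contrast model, with Mauchly's
#' sphericity test and Greenhouse-Geisser epsilon-corrected degrees of
#' freedom. Type III (partial) sums of squares are used throughout, and
#' covariates are z-scored internally (F statistics are invariant to this).
#'
#' @param metricByScale numeric matrix `n_regions x n_scales` of one network
#'   metric (static value or temporal CV) per region and scale; see
#'   [metricByScale()].
#' @param covariates a [RegionalPetVector-class], a list of one or two of
#'   them, or a numeric vector/matrix with one column per covariate.
#' @param metric name of the metric, carried into the result.
#' @param posthoc logical; also compute per-scale (partial) correlations of
#'   the metric with the first covariate, controlling for the second when
#'   present.
#' @param familySize Bonferroni family size for the post-hoc correlations;
#'   default `4 * n_scales` (four metrics by all scales, the per-figure
#'   family).
#'
#' @return An [AssociationResult-class].
#'
#' @examples
#' set.seed(7)
#' y <- matrix(rnorm(82 * 11), 82)
#' pet <- regionalPetVector(runif(82, 1, 3), "rCPS")
#' rmGlm(y, pet)
#'
#' @export
rmGlm <- function(metricByScale, covariates, metric = "metric",
                  posthoc = FALSE, familySize = NULL) {
  Y <- as.matrix(metricByScale)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 within-factor levels (scales)")
  if (anyNA(Y)) stop("metric matrix contains missing values")

  X <- covariateMatrix(covariates, n)
  p <- ncol(X)
  Xz <- scale(X)
  D <- cbind(`(Intercept)` = 1, Xz)
  if (qr(D)$rank < ncol(D))
    stop("collinear covariates: design matrix is rank deficient")

  # --- between-units part: covariate effects on the scale-averaged metric
  ybar <- rowMeans(Y)
  fitFull <- stats::lm.fit(D, ybar)
  sseFull <- sum(fitFull$residuals^2)
  dfeB <- n - 1L - p
  mainRows <- lapply(seq_len(p), function(i) {
    Dred <- D[, -(i + 1L), drop = FALSE]
    sseRed <- sum(stats::lm.fit(Dred, ybar)$residuals^2)
    Fv <- (sseRed - sseFull) / (sseFull / dfeB)
    data.frame(effect = paste0(colnames(X)[i], " (main)"),
               beta = fitFull$coefficients[i + 1L],
               F = Fv, df1 = 1, df2 = dfeB,
               p = stats::pf(Fv, 1, dfeB, lower.tail = FALSE),
               df1GG = NA_real_, df2GG = NA_real_, pGG = NA_real_)
  })

  # --- within-units part: orthonormal contrasts across scales
  C <- orthonormalContrasts(k)
  Yc <- Y %*% C
  # no within-scale variance at all (every scale identical): the within
  # part is vacuous rather than 0/0
  degenerateWithin <- sum(Yc^2) < 1e-20 * max(sum(Y^2), 1)
  Bfull <- solve(crossprod(D), crossprod(D, Yc))
  Rfull <- Yc - D %*% Bfull
  E <- crossprod(Rfull)
  dfeW <- n - p - 1L

  Sigma <- E / dfeW
  eps <- ggEpsilonFromSigma(Sigma)
  mau <- mauchlyFromSigma(Sigma, dfeW)

  withinRow <- function(label, dropCol) {
    Dred <- D[, -dropCol, drop = FALSE]
    Bred <- solve(crossprod(Dred), crossprod(Dred, Yc))
    H <- crossprod(Yc - Dred %*% Bred) - E
    trH <- sum(diag(H)); trE <- sum(diag(E))
    Fv <- if (degenerateWithin) 0
          else (trH / (k - 1)) / (trE / (dfeW * (k - 1)))
    df1 <- k - 1
    df2 <- dfeW * (k - 1)
    data.frame(effect = label, beta = NA_real_,
               F = Fv, df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               df1GG = eps * df1, df2GG = eps * df2,
               pGG = stats::pf(Fv, eps * df1, eps * df2,
                               lower.tail = FALSE))
  }
  scaleRow <- withinRow("scale (within)", dropCol = 1L)
  intRows <- lapply(seq_len(p), function(i)
    withinRow(paste0(colnames(X)[i], " x scale"), dropCol = i + 1L))

  effects <- do.call(rbind, c(mainRows, list(scaleRow), intRows))
  rownames(effects) <- NULL

  ph <- if (posthoc) {
    if (is.null(familySize)) familySize <- 4L * k
    posthocCorrelations(Y, X[, 1L],
                        control = if (p >= 2L) X[, 2L] else NULL,
                        familySize = familySize)
  } else {
    data.frame(scale = integer(), r = numeric(), p = numeric(),
               pBonferroni = numeric(), significant = logical())
  }

  new("AssociationResult", metric = metric, covariates = colnames(X),
      effects = effects, ggEpsilon = eps, mauchlyW = mau$W,
      mauchlyP = mau$p, posthoc = ph)
}

covariateMatrix <- function(covariates, n) {
  asCol <- function(v) {
    if (is(v, "RegionalPetVector")) {
      out <- matrix(petValues(v), ncol = 1L,
                    dimnames = list(NULL, tracer(v)))
    } else {
      out <- matrix(as.numeric(v), ncol = 1L,
                    dimnames = list(NULL, "covariate"))
    }
    out
  }
  X <- if (is(covariates, "RegionalPetVector")) {
    asCol(covariates)
  } else if (is.list(covariates)) {
    cols <- lapply(covariates, asCol)
    out <- do.call(cbind, cols)
    nm <- unlist(lapply(cols, colnames))
    colnames(out) <- make.unique(nm)
    out
  } else if (is.matrix(covariates)) {
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    covariates
  } else {
    asCol(covariates)
  }
  if (nrow(X) != n)
    stop("covariate length (", nrow(X), ") does not match regions (", n, ")")
  if (ncol(X) > 2L) stop("at most two covariates are supported")
  X
}

orthonormalContrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

ggEpsilonFromSigma <- function(Sigma) {
  k1 <- nrow(Sigma)
  if (sum(Sigma^2) < 1e-300) return(1)  # no within variance: trivially spherical
  unname(sum(diag(Sigma))^2 / (k1 * sum(Sigma^2)))
}

mauchlyFromSigma <- function(Sigma, ndf) {
  k1 <- nrow(Sigma)
  if (k1 < 2L || sum(diag(Sigma)) < 1e-300)
    return(list(W = 1, p = 1, df = 0))
  W <- det(Sigma) / (sum(diag(Sigma)) / k1)^k1
  W <- min(max(W, .Machine$double.xmin), 1)
  df <- k1 * (k1 + 1) / 2 - 1
  # Box's chi-square approximation with the usual second-order correction
  rho <- 1 - (2 * k1^2 + k1 + 2) / (6 * k1 * ndf)
  w2 <- (k1 + 2) * (k1 - 1) * (k1 - 2) *
    (2 * k1^3 + 6 * k1^2 + 3 * k1 + 2) / (288 * (ndf * k1 * rho)^2)
  chi2 <- -rho * ndf * log(W)
  p1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  p2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  list(W = W, p = p1 + w2 * (p2 - p1), df = df)
}

#' Mauchly's test of sphericity across scales
#'
#' Mauchly's W on the covariance of the orthonormal within-factor
#' contrasts, with the usual chi-square approximation. Residualizes on the
#' supplied covariates first (intercept only when none are given).
#'
#' @inheritParams rmGlm
#' @return list with `W`, `p`, and the chi-square `df`.
#' @examples
#' mauchlySphericity(matrix(rnorm(40 * 2), 40))$W  # k = 2: exactly 1
#' @export
mauchlySphericity <- function(metricByScale, covariates = NULL) {
  s <- contrastSigma(metricByScale, covariates)
  mauchlyFromSigma(s$Sigma, s$ndf)[c("W", "p", "df")]
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor
#' `epsilon = tr(S)^2 / ((k - 1) * tr(S^2))` on the covariance `S` of the
#' orthonormal within-factor contrasts (equivalently, the double-centered
#' covariance of the scale profiles). Bounded by `1/(k-1)` (maximal
#' violation) and 1 (sphericity holds); equals 1 exactly at `k = 2`.
#'
#' @inheritParams rmGlm
#' @return scalar epsilon.
#' @export
ggEpsilon <- function(metricByScale, covariates = NULL) {
  ggEpsilonFromSigma(contrastSigma(metricByScale, covariates)$Sigma)
}

contrastSigma <- function(metricByScale, covariates = NULL) {
  Y <- as.matrix(metricByScale)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 within-factor levels")
  D <- if (is.null(covariates)) matrix(1, n, 1L)
       else cbind(1, scale(covariateMatrix(covariates, n)))
  Yc <- Y %*% orthonormalContrasts(k)
  B <- solve(crossprod(D), crossprod(D, Yc))
  R <- Yc - D %*% B
  ndf <- n - ncol(D)
  list(Sigma = crossprod(R) / ndf, ndf = ndf)
}

#' Post-hoc per-scale (partial) Pearson correlations
#'
#' Pearson correlation between a network metric and a PET covariate at each
#' wavelet scale, optionally as a first-order partial correlation
#' controlling for a second covariate of no interest:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Two-sided p-values use the t approximation with `n - 2` (plain) or
#' `n - 3` (partial) degrees of freedom; significance flags are
#' Bonferroni-corrected for the stated family size.
#'
#' @param metricPerScale numeric matrix `n_regions x n_scales` (or a single
#'   vector for one scale).
#' @param target covariate of interest ([RegionalPetVector-class] or
#'   numeric).
#' @param control optional covariate of no interest.
#' @param familySize number of tests in the Bonferroni family; default
#'   `4 * n_scales` (all metrics at all scales for one tracer).
#' @param alpha family-wise significance level, default 0.05.
#' @return data.frame: `scale`, `r`, `p`, `pBonferroni`, `significant`.
#' @export
posthocCorrelations <- function(metricPerScale, target, control = NULL,
                                familySize = NULL, alpha = 0.05) {
  Y <- as.matrix(metricPerScale)
  k <- ncol(Y)
  n <- nrow(Y)
  if (is.null(familySize)) familySize <- 4L * k
  x <- if (is(target, "RegionalPetVector")) petValues(target)
       else as.numeric(target)
  z <- if (is.null(control)) NULL
       else if (is(control, "RegionalPetVector")) petValues(control)
       else as.numeric(control)
  if (length(x) != n || (!is.null(z) && length(z) != n))
    stop("covariate length does not match number of regions")

  rows <- lapply(seq_len(k), function(j) {
    y <- Y[, j]
    if (is.null(z)) {
      r <- stats::cor(y, x)
      df <- n - 2L
    } else {
      rxy <- stats::cor(y, x); rxz <- stats::cor(y, z)
      ryz <- stats::cor(x, z)
      if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
        stop("degenerate control covariate (|r| = 1)")
      r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      df <- n - 3L
    }
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    data.frame(scale = j, r = r, p = p,
               pBonferroni = min(1, p * familySize),
               significant = p * familySize < alpha)
  })
  do.call(rbind, rows)
}
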