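#' @include AllClasses.R builders.R simulate.R
NULL

# theta giving an arbitrary target G for the unconstrained one-factorial
# model (lower-triangular Cholesky entries in basis order)
.thetaForUnconstrained <- function(model, G) {
  .projectOntoBasis(model, .safeChol(G))
}

# theta for the two-condition factorial catalogue: per-block 2x2 Cholesky
.thetaForFactorial <- function(varA1, varA2, gammaA, varB1, varB2, gammaB,
                               varD1 = NULL, varD2 = NULL, gammaD = NULL) {
  chol2 <- function(v1, v2, g) {
    t1 <- sqrt(v1)
    t2 <- g / t1
    c(t1, t2, sqrt(max(v2 - t2^2, 0)))
  }
  # basis order within each block: [1,1], [2,1], [2,2]
  th <- c(chol2(varA1, varA2, gammaA), chol2(varB1, varB2, gammaB))
  if (!is.null(varD1)) th <- c(th, chol2(varD1, varD2, gammaD))
  th
}

# 3x3 target covariance of the one-factorial simulations
.oneFactorialG <- function(rho = c(r12 = 0, r13 = -0.2, r23 = 0.8),
                           variances = c(1, 1, 1)) {
  sd <- sqrt(variances)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho[["r12"]]
  R[1, 3] <- R[3, 1] <- rho[["r13"]]
  R[2, 3] <- R[3, 2] <- rho[["r23"]]
  outer(sd, sd) * R
}

#' Simulation scenarios with known component structure
#'
#' Turnkey generators for the simulation studies supported by the package.
#' Each returns the generating [ScenarioTruth-class] together with one
#' sampled [PatternDataset-class]. All scenarios use n = 5 trials per
#' condition (or per condition-by-level cell) and P = 100 voxels unless
#' stated otherwise.
#'
#' \describe{
#'   \item{scenarioOneFactorial}{3 conditions with unit component variances
#'     and true correlations (r12, r13, r23) = (0, -0.2, 0.8); the noise
#'     variance is a free argument (studied over a grid 0.5-10).}
#'   \item{scenarioCommonActivation}{adds a nonspecific component with
#'     variance 4 shared by every trial, plus 5 control trials containing
#'     only that component and noise.}
#'   \item{scenarioTwoFactorial}{2 conditions x 4 levels with level
#'     variances 1, condition variances 2, matched-level covariance 0.5
#'     (true corrected correlation 0.5); the noise variance and the
#'     normalised condition covariance gamma_alpha / sigma_alpha^2 are free
#'     arguments.}
#'   \item{scenarioVoxelSelection}{the two-factorial truth with noise
#'     variance 4 and gamma_alpha = 0, where a fraction of voxels carries no
#'     level-specific signal.}
#'   \item{scenarioSpatial}{the two-factorial truth on a lattice sphere
#'     (radius 3.5 voxels, 179 voxels) with noise variance 3, condition and
#'     level variances 1, gamma_alpha = 0.3, gamma_beta = 0.5, and
#'     squared-exponential spatial fields: condition SD fixed at 1, level
#'     and noise SDs free arguments.}
#' }
#'
#' @param noiseVar trial noise variance.
#' @param seed optional seed for the dataset draw.
#' @param P number of voxels.
#' @param n trials per condition (or cell).
#' @return list with \code{truth} and \code{data}.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenarioOneFactorial <- function(noiseVar = 2, seed = NULL, P = 100L, n = 5L) {
  model <- buildOneFactorial(3L, n)
  G <- .oneFactorialG()
  truth <- new("ScenarioTruth", model = model,
               theta = .thetaForUnconstrained(model, G),
               noiseVar = noiseVar,
               targetCorrelations = c(r12 = 0, r13 = -0.2, r23 = 0.8),
               spatial = NULL, uninformativeFraction = 0,
               trialInfo = data.frame(
                 condition = rep(paste0("s", 1:3), each = n),
                 stringsAsFactors = FALSE),
               coords = NULL, nVoxels = as.numeric(P))
  list(truth = truth, data = sampleDataset(truth, P = P, seed = seed))
}

#' @rdname scenarios
#' @param commonVar variance of the shared activation component.
#' @param controlTrials number of control-condition trials.
#' @export
scenarioCommonActivation <- function(noiseVar = 2, seed = NULL, P = 100L,
                                     n = 5L, commonVar = 4,
                                     controlTrials = 5L) {
  model <- buildCommonPattern(3L, n, controlTrials = controlTrials)
  Gstim <- .oneFactorialG()
  # theta: common SD, then the stimulus-block Cholesky entries
  thStim <- .projectOntoBasis(model, {
    A <- matrix(0, 4, 4)
    A[1, 1] <- sqrt(commonVar)
    A[2:4, 2:4] <- .safeChol(Gstim)
    A
  })
  truth <- new("ScenarioTruth", model = model, theta = thStim,
               noiseVar = noiseVar,
               targetCorrelations = c(r12 = 0, r13 = -0.2, r23 = 0.8),
               spatial = NULL, uninformativeFraction = 0,
               trialInfo = data.frame(
                 condition = c(rep("control", controlTrials),
                               rep(paste0("s", 1:3), each = n)),
                 stringsAsFactors = FALSE),
               coords = NULL, nVoxels = as.numeric(P))
  list(truth = truth, data = sampleDataset(truth, P = P, seed = seed))
}

# trial metadata shared by the factorial scenarios
.factorialTrialInfo <- function(n, conds = c("c1", "c2"), levels = 4L) {
  cond <- rep(conds, each = levels * n)
  level <- rep(rep(paste0("l", seq_len(levels)), each = n), times = length(conds))
  data.frame(condition = paste(cond, level, sep = ":"),
             cond = cond, level = level, stringsAsFactors = FALSE)
}

#' @rdname scenarios
#' @param gammaAlphaRatio normalised condition covariance
#'   gamma_alpha / sigma_alpha^2 in [0, 1).
#' @export
scenarioTwoFactorial <- function(noiseVar = 4, gammaAlphaRatio = 0,
                                 seed = NULL, P = 100L, n = 5L) {
  model <- buildFactorial(2L, 4L, trialsPerCell = n)
  th <- .thetaForFactorial(2, 2, gammaAlphaRatio * 2, 1, 1, 0.5)
  truth <- new("ScenarioTruth", model = model, theta = th,
               noiseVar = noiseVar,
               targetCorrelations = c(rMatched = 0.5),
               spatial = NULL, uninformativeFraction = 0,
               trialInfo = .factorialTrialInfo(n),
               coords = NULL, nVoxels = as.numeric(P))
  list(truth = truth, data = sampleDataset(truth, P = P, seed = seed))
}

#' @rdname scenarios
#' @param fraction fraction of voxels carrying no level-specific signal.
#' @export
scenarioVoxelSelection <- function(fraction = 0, seed = NULL, P = 100L,
                                   n = 5L) {
  model <- buildFactorial(2L, 4L, trialsPerCell = n)
  th <- .thetaForFactorial(2, 2, 0, 1, 1, 0.5)
  truth <- new("ScenarioTruth", model = model, theta = th, noiseVar = 4,
               targetCorrelations = c(rMatched = 0.5),
               spatial = NULL, uninformativeFraction = fraction,
               trialInfo = .factorialTrialInfo(n),
               coords = NULL, nVoxels = as.numeric(P))
  list(truth = truth, data = sampleDataset(truth, P = P, seed = seed))
}

#' @rdname scenarios
#' @param sBeta spatial autocorrelation SD of the level components (voxels).
#' @param sEps spatial autocorrelation SD of the noise (voxels).
#' @param radius sphere radius in voxels.
#' @export
scenarioSpatial <- function(sBeta = 1, sEps = 1, seed = NULL, n = 5L,
                            radius = 3.5) {
  coords <- sphereCoords(radius)
  model <- buildFactorial(2L, 4L, trialsPerCell = n)
  th <- .thetaForFactorial(1, 1, 0.3, 1, 1, 0.5)
  truth <- new("ScenarioTruth", model = model, theta = th, noiseVar = 3,
               targetCorrelations = c(rMatched = 0.5, rAlpha = 0.3),
               spatial = list(sPerBlock = c(condition = 1, level = sBeta),
                              noiseS = sEps, jitter = 1e-8),
               uninformativeFraction = 0,
               trialInfo = .factorialTrialInfo(n),
               coords = coords, nVoxels = as.numeric(nrow(coords)))
  list(truth = truth, data = sampleDataset(truth, seed = seed))
}
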