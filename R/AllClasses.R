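#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' PatternDataset: trial-by-voxel activation estimates with trial metadata
#'
#' Container for an N x P matrix of activation estimates (one row per trial,
#' one column per voxel or feature), per-trial metadata and, optionally,
#' per-voxel spatial coordinates. Rows are assumed to be independent trial
#' estimates (e.g. first-level regression coefficients); columns are treated
#' as samples from the distribution of the underlying pattern components.
#'
#' @slot Y numeric matrix, N trials x P voxels; must be finite.
#' @slot trialInfo data.frame with N rows; must contain a \code{condition}
#'   column; may carry \code{run}, \code{cond}, \code{level} or other
#'   per-trial covariates.
#' @slot coords numeric matrix (P x d, typically d = 3) of voxel coordinates
#'   in mm or voxel units, or NULL when no spatial information is available.
#'
#' @seealso [PatternDataset()] for the user-facing constructor.
#' @exportClass PatternDataset
setClass("PatternDataset",
  representation(Y = "matrix", trialInfo = "data.frame", coords = "matrixOrNULL"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@Y) < 2L) msg <- c(msg, "need at least 2 trials")
    if (ncol(object@Y) < 2L) msg <- c(msg, "need at least 2 voxels")
    if (!all(is.finite(object@Y))) msg <- c(msg, "Y contains non-finite values")
    if (nrow(object@trialInfo) != nrow(object@Y))
      msg <- c(msg, "trialInfo must have one row per trial")
    if (!"condition" %in% names(object@trialInfo))
      msg <- c(msg, "trialInfo must contain a 'condition' column")
    if (!is.null(object@coords) && nrow(object@coords) != ncol(object@Y))
      msg <- c(msg, "coords must have one row per voxel")
    if (length(msg)) msg else TRUE
  })

#' Construct a PatternDataset
#'
#' @param Y numeric matrix of activation estimates (N trials x P voxels).
#' @param condition per-trial condition labels (length N). Ignored when
#'   \code{trialInfo} is supplied.
#' @param run optional per-trial run labels (length N).
#' @param coords optional P x d matrix of voxel coordinates.
#' @param trialInfo optional data.frame of per-trial metadata (must contain a
#'   \code{condition} column); overrides \code{condition}/\code{run}.
#' @return A [PatternDataset-class] object.
#' @examples
#' Y <- matrix(rnorm(20), 4, 5)
#' pd <- PatternDataset(Y, condition = c("a", "a", "b", "b"))
#' nTrials(pd)
#' @export
PatternDataset <- function(Y, condition = NULL, run = NULL, coords = NULL,
                           trialInfo = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(trialInfo)) {
    if (is.null(condition))
      stop("either 'condition' or 'trialInfo' must be given")
    trialInfo <- data.frame(condition = as.character(condition),
                            stringsAsFactors = FALSE)
    if (!is.null(run)) trialInfo$run <- as.character(run)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }
  new("PatternDataset", Y = Y, trialInfo = trialInfo, coords = coords)
}

#' ComponentModel: design matrix and basis-matrix catalogue
#'
#' Encodes a pattern-component model: the N x Q design matrix Z mapping
#' trials onto pattern components, and an ordered set of H basis matrices
#' B_h that parameterise the component square-root factor
#' A(theta) = sum_h theta_h B_h, so that the component covariance
#' G = A A' is positive semi-definite for every theta. The \code{blocks}
#' partition groups component indices into named sets (condition, level,
#' run, ...) used for spatial-kernel estimation and reporting.
#'
#' @slot Z numeric matrix, N x Q design (indicator or parametric entries).
#' @slot basis list of H numeric Q x Q matrices.
#' @slot paramNames character vector of length H.
#' @slot blocks named list of integer vectors partitioning 1..Q.
#' @slot componentNames character vector of length Q.
#'
#' @seealso [buildOneFactorial()], [buildCommonPattern()], [buildFactorial()],
#'   [assembleG()]
#' @exportClass ComponentModel
setClass("ComponentModel",
  representation(Z = "matrix", basis = "list", paramNames = "character",
                 blocks = "list", componentNames = "character"),
  validity = function(object) {
    msg <- character()
    Q <- ncol(object@Z)
    if (length(object@basis) < 1L) msg <- c(msg, "need at least one basis matrix")
    bad <- vapply(object@basis, function(b)
      !is.matrix(b) || nrow(b) != Q || ncol(b) != Q, logical(1))
    if (any(bad)) msg <- c(msg, "all basis matrices must be Q x Q")
    if (length(object@paramNames) != length(object@basis))
      msg <- c(msg, "paramNames must match the number of basis matrices")
    if (length(object@componentNames) != Q)
      msg <- c(msg, "componentNames must have length Q")
    idx <- sort(unlist(object@blocks, use.names = FALSE))
    if (!identical(as.integer(idx), seq_len(Q)))
      msg <- c(msg, "blocks must partition the component indices exactly once")
    if (!length(msg)) {
      # linear independence of the (vectorised) basis matrices
      Bmat <- vapply(object@basis, as.vector, numeric(Q * Q))
      if (qr(Bmat)$rank < length(object@basis))
        msg <- c(msg, "basis matrices must be linearly independent")
    }
    if (length(msg)) msg else TRUE
  })

#' ComponentParams: hyper-parameters of a component model
#'
#' @slot theta numeric length-H vector weighting the basis matrices (units:
#'   square-root of pattern variance).
#' @slot noiseVar non-negative scalar trial noise variance.
#' @exportClass ComponentParams
setClass("ComponentParams",
  representation(theta = "numeric", noiseVar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@noiseVar) != 1L || is.na(object@noiseVar) ||
        object@noiseVar < 0) msg <- c(msg, "noiseVar must be a scalar >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname ComponentParams-class
#' @param theta numeric parameter vector.
#' @param noiseVar noise variance (>= 0).
#' @export
ComponentParams <- function(theta, noiseVar) {
  new("ComponentParams", theta = as.numeric(theta),
      noiseVar = as.numeric(noiseVar))
}

#' PatternFit: a fitted pattern-component model
#'
#' Result of [emFit()]: maximum-likelihood hyper-parameters, the implied
#' component covariance G, the mean coefficients removed before fitting, the
#' marginal log-likelihood trace and the BLUP estimates of the hidden
#' pattern components.
#'
#' @slot model the [ComponentModel-class] that was fitted.
#' @slot theta estimated basis weights.
#' @slot noiseVar estimated noise variance.
#' @slot G Q x Q estimated component covariance (= A A').
#' @slot meanCoef length-Q mean coefficients (activation units).
#' @slot loglikTrace per-iteration marginal log-likelihood (non-decreasing).
#' @slot Uhat Q x P BLUP matrix of the hidden patterns.
#' @slot nIter number of EM iterations run.
#' @slot converged logical; FALSE when the iteration cap was reached.
#' @exportClass PatternFit
setClass("PatternFit",
  representation(model = "ComponentModel", theta = "numeric",
                 noiseVar = "numeric", G = "matrix", meanCoef = "numeric",
                 loglikTrace = "numeric", Uhat = "matrix", nIter = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@noiseVar < 0) msg <- c(msg, "noiseVar must be >= 0")
    d <- diff(object@loglikTrace)
    if (length(d) && any(d < -1e-6 * (abs(object@loglikTrace[-length(object@loglikTrace)]) + 1)))
      msg <- c(msg, "log-likelihood trace must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' SimilarityResult: corrected component correlations
#'
#' @slot variances named per-component variances (diagonal of G).
#' @slot covariances Q x Q covariance matrix (a copy of G).
#' @slot corrected Q x Q matrix of corrected correlations; entries involving
#'   an unstable (near-zero-variance) component are NA.
#' @slot unstable logical vector flagging components whose variance fell
#'   below the stability floor.
#' @exportClass SimilarityResult
setClass("SimilarityResult",
  representation(variances = "numeric", covariances = "matrix",
                 corrected = "matrix", unstable = "logical"))

#' SpatialEstimate: binned autocorrelation and fitted kernel width
#'
#' @slot block name of the component block (or "noise").
#' @slot binEdges distance bin boundaries.
#' @slot binCenters mean pair distance per bin (the abscissa used in fitting).
#' @slot acf per-bin pooled autocorrelation (NA for empty bins).
#' @slot pairCounts number of voxel pairs per bin.
#' @slot s fitted squared-exponential kernel SD (distance units).
#' @slot fwhm 2 sqrt(ln 2) * s, the FWHM of the equivalent smoothing kernel.
#' @slot rss weighted residual sum of squares of the kernel fit.
#' @slot flag "ok", "upper-bound" (s pinned at the search limit) or
#'   "all-negative" (no positive autocorrelation; s set to 0).
#' @exportClass SpatialEstimate
setClass("SpatialEstimate",
  representation(block = "character", binEdges = "numeric",
                 binCenters = "numeric", acf = "numeric",
                 pairCounts = "numeric", s = "numeric", fwhm = "numeric",
                 rss = "numeric", flag = "character"),
  validity = function(object) {
    msg <- character()
    if (object@s < 0) msg <- c(msg, "s must be >= 0")
    if (abs(object@fwhm - 2 * sqrt(log(2)) * object@s) >
        1e-12 * (1 + object@fwhm))
      msg <- c(msg, "fwhm must equal 2*sqrt(ln 2)*s")
    if (any(object@pairCounts < 0)) msg <- c(msg, "pairCounts must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ScenarioTruth: ground truth for a synthetic-data scenario
#'
#' Bundles everything needed to draw datasets with known structure: the
#' component model, the true hyper-parameters, the per-trial metadata, and
#' (optionally) voxel coordinates with per-block spatial autocorrelation SDs.
#'
#' @slot model the generating [ComponentModel-class].
#' @slot theta true basis weights (so the true G is \code{assembleG}).
#' @slot noiseVar true trial noise variance.
#' @slot targetCorrelations named true correlations the scenario is designed
#'   to probe (e.g. \code{c(r23 = 0.8)}).
#' @slot spatial NULL, or a list with \code{sPerBlock} (named numeric, SD of
#'   the spatial autocorrelation per block; 0 = spatially independent),
#'   \code{noiseS} (SD for the noise field) and \code{jitter}.
#' @slot uninformativeFraction fraction of voxels whose level-block
#'   components are zeroed (no condition-specific information).
#' @slot trialInfo per-trial metadata for generated datasets.
#' @slot coords voxel coordinates (required for spatial scenarios) or NULL.
#' @slot nVoxels default number of voxels P for generated datasets.
#' @exportClass ScenarioTruth
setClass("ScenarioTruth",
  representation(model = "ComponentModel", theta = "numeric",
                 noiseVar = "numeric", targetCorrelations = "numeric",
                 spatial = "listOrNULL", uninformativeFraction = "numeric",
                 trialInfo = "data.frame", coords = "matrixOrNULL",
                 nVoxels = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@noiseVar < 0) msg <- c(msg, "noiseVar must be >= 0")
    f <- object@uninformativeFraction
    if (length(f) != 1L || f < 0 || f >= 1)
      msg <- c(msg, "uninformativeFraction must lie in [0, 1)")
    if (!is.null(object@spatial)) {
      if (is.null(object@coords))
        msg <- c(msg, "spatial scenarios require voxel coordinates")
      if (any(unlist(object@spatial[c("sPerBlock", "noiseS")]) < 0))
        msg <- c(msg, "spatial SDs must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })
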