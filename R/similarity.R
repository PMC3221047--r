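#' @include AllClasses.R
NULL

#' Corrected correlations between pattern components
#'
#' Converts a component covariance matrix G (estimated or true) into the
#' matrix of corrected correlations rho_ij = gamma_ij / (sigma_i sigma_j).
#' Because G is estimated directly, these correlations refer to the hidden
#' pattern components and are invariant to the noise level, nonspecific
#' activation and voxel selection. Components whose variance falls below
#' \code{floor} times the mean variance are flagged unstable and their
#' correlations returned as NA (the normalised coefficient has exploding
#' variance when the component variance approaches zero).
#'
#' @param G Q x Q symmetric PSD matrix, or a [PatternFit-class].
#' @param floor relative variance threshold for the stability flag.
#' @return A [SimilarityResult-class].
#' @examples
#' correctedCorrelations(rbind(c(1, 0.5), c(0.5, 1)))
#' @export
correctedCorrelations <- function(G, floor = 1e-6) {
  if (is(G, "PatternFit")) G <- G@G
  G <- as.matrix(G)
  v <- diag(G)
  unstable <- v < floor * mean(v)
  sd <- sqrt(ifelse(unstable, NA_real_, v))
  corrected <- G / outer(sd, sd)
  diag(corrected)[!unstable] <- 1
  if (!is.null(rownames(G))) names(v) <- rownames(G)
  new("SimilarityResult", variances = v, covariances = G,
      corrected = corrected, unstable = unstable)
}

# per-condition mean patterns: rows = conditions (in first-appearance order)
.conditionMeans <- function(data, labels = NULL) {
  Y <- data@Y
  if (is.null(labels)) labels <- data@trialInfo$condition
  lev <- unique(labels)
  out <- t(vapply(lev, function(l) colMeans(Y[labels == l, , drop = FALSE]),
                  numeric(ncol(Y))))
  rownames(out) <- lev
  out
}

#' Sample correlations between condition mean patterns
#'
#' The naive similarity estimator: the Pearson correlation (over voxels)
#' between the per-condition mean activation patterns. Measurement noise in
#' the means shrinks these correlations towards zero (see
#' [expectedSampleCorr()]), so they are not comparable across regions with
#' different noise levels.
#'
#' @param data a [PatternDataset-class].
#' @param labels optional per-trial labels overriding the condition column.
#' @return condition x condition correlation matrix; entries involving a
#'   zero-variance mean pattern are NA.
#' @export
sampleCorrMeanPatterns <- function(data, labels = NULL) {
  M <- .conditionMeans(data, labels)
  sds <- apply(M, 1, stats::sd)
  R <- suppressWarnings(stats::cor(t(M)))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  R
}

#' Correlations after subtracting a control condition's mean pattern
#'
#' Subtracts the mean pattern of a measured control condition (an estimate
#' of the shared, nonspecific activation) from every other condition mean,
#' then correlates the residual patterns. Because the control mean itself
#' contains noise, subtracting the same noisy pattern from all conditions
#' induces an upward bias that grows with the noise level.
#'
#' @param data a [PatternDataset-class].
#' @param controlLabel the condition label of the control trials.
#' @return correlation matrix over the non-control conditions.
#' @export
controlSubtractedCorr <- function(data, controlLabel) {
  M <- .conditionMeans(data)
  if (!controlLabel %in% rownames(M))
    stop("control condition '", controlLabel, "' not present")
  resid <- sweep(M[rownames(M) != controlLabel, , drop = FALSE], 2,
                 M[controlLabel, ])
  suppressWarnings(stats::cor(t(resid)))
}

#' Correlations after subtracting per-condition mean patterns
#'
#' For a factorial design: removes each condition's mean pattern (averaged
#' over its levels) from the level-specific cell means of that condition,
#' then correlates the residual cell patterns. This fixed-effects attempt to
#' strip the nonspecific component ignores the noise in the subtracted mean
#' and induces a negative bias that grows with the noise level.
#'
#' @param data a [PatternDataset-class] whose trialInfo contains \code{cond}
#'   (the first factor) and \code{level} (the second factor) columns, or
#'   explicit vectors via \code{cond}/\code{level}.
#' @param cond,level optional per-trial factor vectors.
#' @return cell x cell correlation matrix of the residual patterns, with
#'   dimnames "cond:level".
#' @export
conditionMeanSubtractedCorr <- function(data, cond = NULL, level = NULL) {
  ti <- data@trialInfo
  if (is.null(cond)) cond <- ti$cond
  if (is.null(level)) level <- ti$level
  if (is.null(cond) || is.null(level))
    stop("need 'cond' and 'level' factors (trialInfo columns or arguments)")
  if (length(unique(level)) < 2)
    stop("need at least 2 levels per condition")
  cells <- paste(cond, level, sep = ":")
  M <- .conditionMeans(data, cells)
  condOfCell <- sub(":.*$", "", rownames(M))
  for (cc in unique(condOfCell)) {
    idx <- condOfCell == cc
    M[idx, ] <- sweep(M[idx, , drop = FALSE], 2,
                      colMeans(M[idx, , drop = FALSE]))
  }
  suppressWarnings(stats::cor(t(M)))
}

#' Expected sample correlation between two condition mean patterns
#'
#' Closed form for the expectation of the naive estimator: with n trials per
#' condition the mean pattern carries residual noise variance
#' sigma_eps^2 / n, so
#' E(r) = gamma / sqrt((sigma_i^2 + sigma_eps^2/n)(sigma_j^2 + sigma_eps^2/n)).
#' For equal component variances this reduces to
#' gamma / (sigma_i sigma_j + sigma_eps^2/n).
#'
#' @param gamma true covariance between the two components.
#' @param sigmaI,sigmaJ component standard deviations (> 0).
#' @param noiseVar trial noise variance.
#' @param n trials per condition.
#' @return scalar expected sample correlation.
#' @examples
#' expectedSampleCorr(0.8, 1, 1, 10, 5)  # 0.2667
#' @export
expectedSampleCorr <- function(gamma, sigmaI, sigmaJ, noiseVar, n) {
  stopifnot(n >= 1, sigmaI > 0, sigmaJ > 0)
  gamma / sqrt((sigmaI^2 + noiseVar / n) * (sigmaJ^2 + noiseVar / n))
}

#' Expected cross-condition sample correlation in the factorial model
#'
#' Closed form for the naive correlation between the measured mean patterns
#' of the two conditions in the condition x level design: for the same level
#' (matched) the numerator is gamma_alpha + gamma_beta, for different levels
#' it is gamma_alpha alone; the denominator contains the full measured
#' variances including noise.
#'
#' @param gammaAlpha covariance of the condition (nonspecific) components.
#' @param gammaBeta matched-level covariance of the level components.
#' @param varAlpha1,varAlpha2 condition component variances.
#' @param varBeta1,varBeta2 level component variances.
#' @param noiseVar trial noise variance.
#' @param n trials per condition-by-level cell.
#' @param matched TRUE for same-level, FALSE for different-level pairs.
#' @return scalar expected sample correlation.
#' @examples
#' expectedCrossConditionCorr(0, 0.5, 2, 2, 1, 1, 0, 5)  # 0.5 / 3
#' @export
expectedCrossConditionCorr <- function(gammaAlpha, gammaBeta,
                                       varAlpha1, varAlpha2,
                                       varBeta1, varBeta2,
                                       noiseVar, n, matched = TRUE) {
  stopifnot(varAlpha1 > 0 || varBeta1 > 0, n >= 1)
  num <- gammaAlpha + if (matched) gammaBeta else 0
  num / sqrt((varAlpha1 + varBeta1 + noiseVar / n) *
             (varAlpha2 + varBeta2 + noiseVar / n))
}

#' Classical multidimensional scaling of a similarity structure
#'
#' Embeds stimuli in a low-dimensional space whose distances reproduce the
#' dissimilarities d = 1 - rho, using classical (Torgerson) scaling: the
#' doubly centred -d^2/2 matrix is eigendecomposed and the coordinates are
#' taken from the leading eigenpairs. The eigenvalue spectrum indicates how
#' many dimensions the similarity structure needs. Sign indeterminacy is
#' resolved by making the first stimulus's coordinate non-negative on every
#' axis.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param nDims number of embedding dimensions.
#' @return list with \code{coords} (stimuli x nDims) and \code{eig}
#'   (all eigenvalues of the centred matrix).
#' @export
mdsEmbed <- function(corr, nDims = 2L) {
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  d <- 1 - corr
  fit <- stats::cmdscale(stats::as.dist(d), k = min(nDims, nrow(corr) - 1L),
                         eig = TRUE)
  X <- fit$points
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  for (j in seq_len(ncol(X))) if (X[1, j] < 0) X[, j] <- -X[, j]
  if (ncol(X) < nDims)
    X <- cbind(X, matrix(0, nrow(X), nDims - ncol(X)))
  rownames(X) <- rownames(corr)
  list(coords = X, eig = fit$eig)
}
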