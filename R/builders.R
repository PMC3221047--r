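#' @include AllClasses.R
NULL

# elementary Q x Q matrix with a single 1 at (i, j)
.E <- function(Q, i, j) {
  B <- matrix(0, Q, Q)
  B[i, j] <- 1
  B
}

# lower-triangular basis catalogue over the component indices `idx`
# (columns restricted to `idx` as well), i.e. an unconstrained PSD block
.lowerTriBasis <- function(Q, idx, prefix = "A") {
  basis <- list()
  nm <- character()
  for (jj in seq_along(idx)) {
    for (ii in jj:length(idx)) {
      basis[[length(basis) + 1L]] <- .E(Q, idx[ii], idx[jj])
      nm <- c(nm, sprintf("%s[%d,%d]", prefix, ii, jj))
    }
  }
  list(basis = basis, names = nm)
}

#' One-factorial component model with unconstrained covariance
#'
#' Builds the model for a single factor with \code{nLevels} conditions and
#' \code{trialsPerLevel} repeated trials per condition. The design matrix Z
#' is the indicator matrix of conditions (trials ordered by condition), and
#' the component covariance G is left unconstrained: the square-root factor
#' A is parameterised as a full lower-triangular matrix, giving
#' H = K(K+1)/2 free parameters for K conditions.
#'
#' @param nLevels number of conditions (>= 2).
#' @param trialsPerLevel trials per condition (>= 1).
#' @return A [ComponentModel-class].
#' @examples
#' m <- buildOneFactorial(3, 5)
#' dim(designMatrix(m))   # 15 x 3
#' length(basisMatrices(m)) # 6
#' @export
buildOneFactorial <- function(nLevels, trialsPerLevel) {
  if (nLevels < 2) stop("invalid design: need at least 2 levels")
  if (trialsPerLevel < 1) stop("invalid design: need at least 1 trial per level")
  Z <- kronecker(diag(nLevels), rep(1, trialsPerLevel))
  lt <- .lowerTriBasis(nLevels, seq_len(nLevels))
  new("ComponentModel", Z = Z, basis = lt$basis, paramNames = lt$names,
      blocks = list(stimulus = seq_len(nLevels)),
      componentNames = paste0("s", seq_len(nLevels)))
}

#' One-factorial model with a shared (common) activation component
#'
#' Adds a nonspecific pattern component, loaded by every trial, to the
#' one-factorial model. The common component is constrained to be
#' uncorrelated with the stimulus-specific components, so the first row and
#' column of G are zero off the diagonal. Its variance is identified either
#' by control trials that contain only the common component plus noise, or
#' (without a control condition) by anchoring: declaring one or more pairs of
#' stimulus components to be uncorrelated, which removes the corresponding
#' off-diagonal degrees of freedom from A.
#'
#' @param nLevels number of stimulus conditions (>= 2).
#' @param trialsPerLevel trials per stimulus condition.
#' @param controlTrials number of control trials (may be 0 if anchors given).
#' @param anchorPairs list of integer pairs (i, j), i < j, of stimulus
#'   components whose covariance is forced to zero. With the triangular
#'   factor the structural zero is exact when i = 1 or when all preceding
#'   off-diagonal entries of row j are also anchored; otherwise the pair
#'   still removes one degree of freedom.
#' @return A [ComponentModel-class] with Q = nLevels + 1 components; the
#'   common component is component 1.
#' @examples
#' m <- buildCommonPattern(3, 5, controlTrials = 5)
#' dim(designMatrix(m))   # 20 x 4
#' @export
buildCommonPattern <- function(nLevels, trialsPerLevel, controlTrials = 0L,
                               anchorPairs = list()) {
  if (nLevels < 2) stop("invalid design: need at least 2 levels")
  if (controlTrials == 0L && length(anchorPairs) == 0L)
    stop(paste("unidentifiable model: without control trials the similarity",
               "scores must be anchored by at least one uncorrelated pair"))
  Q <- nLevels + 1L
  Zstim <- cbind(1, kronecker(diag(nLevels), rep(1, trialsPerLevel)))
  Zctrl <- matrix(0, controlTrials, Q)
  if (controlTrials > 0) Zctrl[, 1] <- 1
  Z <- rbind(Zctrl, Zstim)
  lt <- .lowerTriBasis(Q, 2:Q, prefix = "S")
  if (length(anchorPairs)) {
    drop <- vapply(anchorPairs, function(p) {
      p <- sort(as.integer(p))
      sprintf("S[%d,%d]", p[2], p[1])
    }, character(1))
    keep <- !(lt$names %in% drop)
    if (all(keep)) stop("anchorPairs did not match any stimulus pair")
    lt$basis <- lt$basis[keep]
    lt$names <- lt$names[keep]
  }
  basis <- c(list(.E(Q, 1, 1)), lt$basis)
  new("ComponentModel", Z = Z, basis = basis,
      paramNames = c("common", lt$names),
      blocks = list(common = 1L, stimulus = 2:Q),
      componentNames = c("common", paste0("s", seq_len(nLevels))))
}

#' Two-factorial component model (condition x level, optional run effect)
#'
#' Encodes the factorial structure in which each condition c carries a
#' nonspecific component u_alpha[c] shared by all its trials, and each
#' condition-by-level cell carries a specific component u_beta[c, l]. The
#' covariance is constrained so that: the alpha block is unconstrained
#' (per-condition variances plus their covariance gamma_alpha); the beta
#' variances are equal across levels within a condition; only beta
#' components of the *same* level share a cross-condition covariance
#' gamma_beta; and alpha and beta components are uncorrelated. With runs,
#' an extra per-run, per-condition component is added (variances shared
#' across runs, within-run cross-condition covariance gamma_delta,
#' uncorrelated across runs), capturing correlated estimation error among
#' trials of the same run.
#'
#' @param nConditions number of conditions (the constrained structure is
#'   validated for 2; more conditions use the same per-level triangular
#'   parameterisation).
#' @param nLevels number of levels of the second factor.
#' @param trialsPerCell trials per condition-by-level cell (ignored when
#'   \code{nRuns} is given: then each cell occurs once per run).
#' @param nRuns optional number of runs.
#' @return A [ComponentModel-class] with components ordered alpha[1..C],
#'   beta[1,1..L], ..., beta[C,1..L], then delta[1..C] per run.
#' @examples
#' m <- buildFactorial(2, 4)        # Q = 10, H = 6
#' m7 <- buildFactorial(2, 4, nRuns = 7)  # Q = 24, H = 9
#' @export
buildFactorial <- function(nConditions = 2L, nLevels = 4L, trialsPerCell = 5L,
                           nRuns = NULL) {
  C <- as.integer(nConditions); L <- as.integer(nLevels)
  if (C < 2) stop("invalid design: need at least 2 conditions")
  if (L < 2) stop("invalid design: need at least 2 levels")
  if (!is.null(nRuns) && (length(nRuns) != 1L || nRuns < 1))
    stop("invalid design: nRuns must be a positive count")
  Q <- C + C * L + if (is.null(nRuns)) 0L else C * as.integer(nRuns)
  aIdx <- seq_len(C)
  bIdx <- function(c, l) C + (c - 1L) * L + l

  # one cell (c, l) trial row of Z
  zRow <- function(c, l, run = NULL) {
    z <- numeric(Q)
    z[c] <- 1
    z[bIdx(c, l)] <- 1
    if (!is.null(run)) z[C + C * L + (run - 1L) * C + c] <- 1
    z
  }
  rows <- list(); cellCond <- integer(); cellLev <- integer(); cellRun <- integer()
  if (is.null(nRuns)) {
    for (c in seq_len(C)) for (l in seq_len(L)) for (t in seq_len(trialsPerCell)) {
      rows[[length(rows) + 1L]] <- zRow(c, l)
      cellCond <- c(cellCond, c); cellLev <- c(cellLev, l)
    }
  } else {
    for (r in seq_len(nRuns)) for (c in seq_len(C)) for (l in seq_len(L)) {
      rows[[length(rows) + 1L]] <- zRow(c, l, r)
      cellCond <- c(cellCond, c); cellLev <- c(cellLev, l)
      cellRun <- c(cellRun, r)
    }
  }
  Z <- do.call(rbind, rows)

  # alpha block: unconstrained lower-triangular C x C
  lt <- .lowerTriBasis(Q, aIdx, prefix = "alpha")
  basis <- lt$basis; nm <- lt$names
  # beta block: per-level C x C lower-triangular factors with parameters
  # shared across levels (equal variances across levels within condition,
  # matched-level cross-condition covariance only)
  for (jj in seq_len(C)) {
    for (ii in jj:C) {
      B <- matrix(0, Q, Q)
      for (l in seq_len(L)) B[bIdx(ii, l), bIdx(jj, l)] <- 1
      basis[[length(basis) + 1L]] <- B
      nm <- c(nm, sprintf("beta[%d,%d]", ii, jj))
    }
  }
  # delta block: per-run C x C lower-triangular factors shared across runs
  if (!is.null(nRuns)) {
    dIdx <- function(c, r) C + C * L + (r - 1L) * C + c
    for (jj in seq_len(C)) {
      for (ii in jj:C) {
        B <- matrix(0, Q, Q)
        for (r in seq_len(nRuns)) B[dIdx(ii, r), dIdx(jj, r)] <- 1
        basis[[length(basis) + 1L]] <- B
        nm <- c(nm, sprintf("delta[%d,%d]", ii, jj))
      }
    }
  }
  cn <- c(paste0("alpha", seq_len(C)),
          unlist(lapply(seq_len(C), function(c) paste0("beta", c, ".", seq_len(L)))))
  blocks <- list(condition = aIdx, level = (C + 1L):(C + C * L))
  if (!is.null(nRuns)) {
    cn <- c(cn, unlist(lapply(seq_len(nRuns), function(r)
      paste0("delta", seq_len(C), ".run", r))))
    blocks$run <- (C + C * L + 1L):Q
  }
  new("ComponentModel", Z = Z, basis = basis, paramNames = nm,
      blocks = blocks, componentNames = cn)
}

#' Assemble the component covariance G from basis weights
#'
#' Computes A = sum_h theta_h B_h and returns G = A A', which is symmetric
#' positive semi-definite for every theta.
#'
#' @param model a [ComponentModel-class].
#' @param theta numeric vector of length H (or a [ComponentParams-class]).
#' @return A Q x Q covariance matrix with component names as dimnames.
#' @examples
#' m <- buildOneFactorial(2, 1)
#' assembleG(m, c(1, 0.5, 1))
#' @export
assembleG <- function(model, theta) {
  if (is(theta, "ComponentParams")) theta <- theta@theta
  A <- assembleA(model, theta)
  G <- tcrossprod(A)
  dimnames(G) <- list(model@componentNames, model@componentNames)
  G
}

#' @rdname assembleG
#' @export
assembleA <- function(model, theta) {
  if (is(theta, "ComponentParams")) theta <- theta@theta
  H <- length(model@basis)
  if (length(theta) != H)
    stop("dimension mismatch: theta must have length ", H)
  Q <- ncol(model@Z)
  A <- matrix(0, Q, Q)
  for (h in seq_len(H)) A <- A + theta[h] * model@basis[[h]]
  A
}

# least-squares projection of a factor matrix A0 onto the basis span:
# theta minimising || sum_h theta_h B_h - A0 ||_F
.projectOntoBasis <- function(model, A0) {
  H <- length(model@basis)
  M <- matrix(0, H, H)
  b <- numeric(H)
  for (h in seq_len(H)) {
    for (g in h:H) {
      M[h, g] <- M[g, h] <- sum(model@basis[[h]] * model@basis[[g]])
    }
    b[h] <- sum(model@basis[[h]] * A0)
  }
  .symSolve(M, b)
}
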