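#' @include AllClasses.R builders.R utils.R
NULL

#' Draw rows of a spatially autocorrelated Gaussian field
#'
#' Each row is a unit-variance Gaussian field over the voxels with
#' squared-exponential spatial correlation exp(-delta^2 / (2 s^2)) between
#' voxels at distance delta. s = 0 (or missing coordinates) yields i.i.d.
#' standard normal entries. The correlation matrix is factorised once per
#' (coords, s) pair and cached, with a small diagonal jitter for numerical
#' positive definiteness.
#'
#' @param coords P x d voxel coordinates.
#' @param s autocorrelation SD in coordinate units (>= 0).
#' @param nRows number of independent field rows to draw.
#' @param seed optional seed (RNG state restored afterwards).
#' @param jitter diagonal regularisation added before Cholesky.
#' @return nRows x P matrix.
#' @export
smoothField <- function(coords, s, nRows, seed = NULL, jitter = 1e-8) {
  if (s < 0) stop("s must be >= 0")
  coords <- as.matrix(coords)
  P <- nrow(coords)
  .withSeed(seed, {
    if (s == 0 || P == 1L)
      return(matrix(stats::rnorm(nRows * P), nRows, P))
    ch <- .sqExpChol(coords, s, jitter)
    matrix(stats::rnorm(nRows * P), nRows, P) %*% ch
  })
}

#' All integer lattice points within a sphere
#'
#' Enumerates the integer lattice coordinates with Euclidean norm at most
#' \code{radius}, centred at the origin — a simple spherical region of
#' interest. Radius 1 gives 7 voxels, 1.5 gives 19, and 3.5 gives 179.
#'
#' @param radius sphere radius in voxel units (> 0).
#' @return matrix with columns x, y, z.
#' @export
sphereCoords <- function(radius) {
  if (radius <= 0) stop("radius must be > 0")
  r <- floor(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  out <- g[sqrt(rowSums(g^2)) <= radius, , drop = FALSE]
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

#' Draw a dataset from a scenario's generative truth
#'
#' Samples the hidden pattern components U block by block: a unit-variance
#' (optionally spatially autocorrelated) Gaussian field is drawn for each
#' block and coloured by the square root of that block's G sub-matrix —
#' valid because cross-block covariances are structurally zero and the
#' spatial model is separable (G kron Sigma). A fraction of voxels can be
#' made uninformative by zeroing their level-block components. The data are
#' Y = Z U + E with i.i.d. (or spatially coloured) Gaussian trial noise.
#'
#' @param truth a [ScenarioTruth-class].
#' @param P number of voxels (defaults to the scenario's \code{nVoxels} or
#'   the number of coordinate rows).
#' @param seed optional seed; the draw is fully reproducible given
#'   (truth, P, seed).
#' @return A [PatternDataset-class].
#' @export
sampleDataset <- function(truth, P = NULL, seed = NULL) {
  .withSeed(seed, {
    model <- truth@model
    coords <- truth@coords
    if (is.null(P)) P <- if (!is.null(coords)) nrow(coords) else truth@nVoxels
    if (P < 2) stop("invalid P")
    if (!is.null(coords) && nrow(coords) != P)
      stop("P must match the coordinate rows for spatial scenarios")
    G <- assembleG(model, truth@theta)
    Q <- ncol(model@Z)
    U <- matrix(0, Q, P)
    sPer <- if (!is.null(truth@spatial)) truth@spatial$sPerBlock else NULL
    jitter <- if (!is.null(truth@spatial)) truth@spatial$jitter else 1e-8
    for (bl in names(model@blocks)) {
      idx <- model@blocks[[bl]]
      s <- if (!is.null(sPer) && bl %in% names(sPer)) sPer[[bl]] else 0
      F <- if (s > 0) smoothField(coords, s, length(idx), jitter = jitter)
           else matrix(stats::rnorm(length(idx) * P), length(idx), P)
      U[idx, ] <- .psdSqrt(G[idx, idx, drop = FALSE]) %*% F
    }
    f <- truth@uninformativeFraction
    if (f > 0 && "level" %in% names(model@blocks)) {
      k <- round(f * P)
      if (k > 0) U[model@blocks$level, seq_len(k)] <- 0
    }
    noiseS <- if (!is.null(truth@spatial)) truth@spatial$noiseS else 0
    N <- nrow(model@Z)
    E <- if (noiseS > 0) {
      sqrt(truth@noiseVar) * smoothField(coords, noiseS, N, jitter)
    } else {
      matrix(stats::rnorm(N * P, sd = sqrt(truth@noiseVar)), N, P)
    }
    Y <- model@Z %*% U + E
    PatternDataset(Y, trialInfo = truth@trialInfo, coords = coords)
  })
}
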