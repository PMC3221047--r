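#' @include AllClasses.R
NULL

#' Assign voxel pairs to distance bins
#'
#' Computes all pairwise Euclidean distances between voxels and assigns each
#' unordered pair to the half-open bin [lo, hi) defined by consecutive
#' \code{edges}. Pairs outside the edge range are dropped.
#'
#' @param coords P x d matrix of voxel coordinates.
#' @param edges strictly increasing bin boundaries, starting above 0.
#' @return list with per-bin components \code{pairs} (2-column index
#'   matrices), \code{counts}, \code{meanDist} (mean pair distance, used as
#'   the bin abscissa) and \code{edges}.
#' @export
pairwiseDistanceBins <- function(coords, edges) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 voxels")
  if (any(diff(edges) <= 0) || edges[1] <= 0)
    stop("edges must be strictly increasing and start above 0")
  D <- as.matrix(stats::dist(coords))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  nb <- length(edges) - 1L
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  bin[d >= edges[nb + 1L]] <- 0L          # beyond the last edge
  pairs <- vector("list", nb)
  meanDist <- rep(NA_real_, nb)
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    pairs[[b]] <- iu[sel, , drop = FALSE]
    counts[b] <- sum(sel)
    if (counts[b]) meanDist[b] <- mean(d[sel])
  }
  list(pairs = pairs, counts = counts, meanDist = meanDist, edges = edges)
}

# default bins adapted to an integer lattice: nearest neighbours, diagonal
# neighbours, then unit-width bins out to the maximum distance
.defaultBinEdges <- function(coords) {
  D <- stats::dist(coords)
  maxd <- max(D)
  if (max(abs(coords - round(coords))) < 1e-8) {
    e <- c(0.5, 1.2, 1.6, seq(2.5, ceiling(maxd) + 0.5, by = 1))
  } else {
    e <- seq(1e-6, maxd * 1.0001, length.out = 12L)
  }
  e[e <= maxd * 1.0001 + 1]
}

#' Pooled spatial autocorrelation of pattern rows
#'
#' Estimates the spatial autocorrelation function of a set of pattern rows
#' (e.g. the BLUP rows of one component block, or trial residuals). Each row
#' is scaled to unit root-mean-square; the per-bin value is the mean product
#' over all voxel pairs in the bin and all rows, weighting each pair
#' equally. By default rows are *not* centred over voxels: the pattern
#' components and residuals this is designed for are zero-mean over voxels
#' by model construction, and subtracting the sample mean of a smooth field
#' over a small region would bias the autocorrelation downward by the
#' field's average pairwise correlation. Set \code{center = TRUE} for
#' patterns with a non-negligible mean.
#'
#' @param U rows x P matrix of patterns (rows of one component block).
#' @param coords P x d voxel coordinates.
#' @param edges bin boundaries; defaults to lattice-adapted bins.
#' @param center subtract each row's mean before pooling (default FALSE).
#' @return list with \code{acf}, \code{pairCounts}, \code{binCenters} (mean
#'   pair distance per bin), and \code{edges}. Empty bins yield NA.
#' @export
componentAcf <- function(U, coords, edges = NULL, center = FALSE) {
  U <- rbind(U)
  if (is.null(edges)) edges <- .defaultBinEdges(coords)
  bins <- pairwiseDistanceBins(coords, edges)
  V <- U
  keep <- rep(TRUE, nrow(U))
  for (r in seq_len(nrow(U))) {
    v <- U[r, ]
    if (center) {
      vc <- v - mean(v)
      if (stats::sd(vc) > 0) v <- vc   # constant patterns stay uncentred
    }
    rms <- sqrt(mean(v^2))
    if (rms == 0) keep[r] <- FALSE else V[r, ] <- v / rms
  }
  V <- V[keep, , drop = FALSE]
  if (nrow(V) == 0) stop("no usable (non-degenerate) rows")
  nb <- length(bins$counts)
  acf <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    if (bins$counts[b] == 0) next
    ij <- bins$pairs[[b]]
    acf[b] <- mean(V[, ij[, 1], drop = FALSE] * V[, ij[, 2], drop = FALSE])
  }
  list(acf = acf, pairCounts = bins$counts, binCenters = bins$meanDist,
       edges = edges)
}

#' Fit a squared-exponential kernel to binned autocorrelation values
#'
#' Weighted least-squares fit of corr(delta) = exp(-delta^2 / (2 s^2)) to
#' the binned sample autocorrelation, minimising over s in
#' [0, max distance]. The fit uses the raw autocorrelation values (not their
#' logs) so negative sample values are tolerated. Deterministic given its
#' inputs.
#'
#' @param acf per-bin autocorrelation values (NA bins are dropped).
#' @param centers per-bin distances.
#' @param weights per-bin weights, typically pair counts.
#' @return list with \code{s}, \code{rss} and \code{flag} ("ok",
#'   "upper-bound" when s is pinned at the search limit, "all-negative" when
#'   no positive autocorrelation exists and s = 0 is returned).
#' @export
fitSqExp <- function(acf, centers, weights = NULL) {
  ok <- is.finite(acf) & is.finite(centers)
  acf <- acf[ok]; centers <- centers[ok]
  if (is.null(weights)) weights <- rep(1, length(acf)) else weights <- weights[ok]
  if (length(acf) < 2) stop("need at least 2 usable bins")
  sse <- function(s) {
    k <- if (s <= 0) as.numeric(centers == 0) else exp(-centers^2 / (2 * s^2))
    sum(weights * (acf - k)^2)
  }
  if (all(acf <= 0))
    return(list(s = 0, rss = sse(0), flag = "all-negative"))
  upper <- max(centers)
  opt <- stats::optimize(sse, interval = c(1e-6, upper), tol = 1e-8)
  s <- opt$minimum; rss <- opt$objective
  if (sse(0) < rss) { s <- 0; rss <- sse(0) }
  flag <- if (s > 0.995 * upper) "upper-bound" else "ok"
  list(s = s, rss = rss, flag = flag)
}

#' FWHM of the smoothing kernel equivalent to an autocorrelation SD
#'
#' A Gaussian autocorrelation function with SD s arises from smoothing
#' spatially independent noise with a Gaussian kernel of SD s / sqrt(2);
#' that kernel's full width at half maximum is FWHM = 2 sqrt(ln 2) s.
#'
#' @param s autocorrelation SD (>= 0), in the coordinate units.
#' @return FWHM in the same units.
#' @examples
#' fwhmFromS(2)  # 3.33 voxels
#' @export
fwhmFromS <- function(s) {
  if (any(s < 0)) stop("s must be >= 0")
  2 * sqrt(log(2)) * s
}

#' Two-step spatial smoothness estimates for a fitted model
#'
#' Implements the approximate two-step procedure: the component covariances
#' are estimated ignoring spatial structure, then the spatial
#' autocorrelation of each component block is measured from the
#' corresponding BLUP rows and summarised by a squared-exponential kernel
#' SD. The noise estimate uses the ordinary-least-squares trial residuals
#' (I - Z Z^+) Y, which contain no leakage from the (possibly smooth)
#' signal components and therefore isolate the noise field's own spatial
#' structure.
#'
#' @param fit a [PatternFit-class].
#' @param data the [PatternDataset-class] the model was fitted to (must
#'   carry voxel coordinates).
#' @param edges optional distance bin boundaries.
#' @param blocks which blocks to estimate (default: all blocks plus noise).
#' @return named list of [SpatialEstimate-class] objects.
#' @export
estimateSmoothness <- function(fit, data, edges = NULL, blocks = NULL) {
  coords <- data@coords
  if (is.null(coords)) stop("dataset carries no voxel coordinates")
  if (is.null(edges)) edges <- .defaultBinEdges(coords)
  model <- fit@model
  Yc <- removeMean(data, model)$centered
  rowsOf <- c(lapply(model@blocks, function(idx)
    fit@Uhat[idx, , drop = FALSE]),
    list(noise = Yc - model@Z %*% (MASS::ginv(model@Z) %*% Yc)))
  if (!is.null(blocks)) rowsOf <- rowsOf[blocks]
  out <- lapply(names(rowsOf), function(bl) {
    a <- componentAcf(rowsOf[[bl]], coords, edges)
    f <- fitSqExp(a$acf, a$binCenters, a$pairCounts)
    new("SpatialEstimate", block = bl, binEdges = a$edges,
        binCenters = a$binCenters, acf = a$acf,
        pairCounts = as.numeric(a$pairCounts), s = f$s,
        fwhm = fwhmFromS(f$s), rss = f$rss, flag = f$flag)
  })
  names(out) <- names(rowsOf)
  out
}
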