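#' @include AllClasses.R builders.R utils.R
NULL

#' Remove the component means from a dataset
#'
#' Each pattern component has its own mean activation level over voxels.
#' Because the mean estimates do not depend on G, they are removed up front:
#' the voxel-averaged trial vector is regressed on Z via the pseudo-inverse,
#' a = Z^+ rowMeans(Y), and Z a is subtracted from every voxel column.
#'
#' @param data a [PatternDataset-class] (or plain N x P matrix).
#' @param model a [ComponentModel-class] supplying the design Z.
#' @return list with \code{meanCoef} (length-Q vector a, activation units)
#'   and \code{centered} (the mean-removed N x P matrix).
#' @export
removeMean <- function(data, model) {
  Y <- if (is(data, "PatternDataset")) data@Y else as.matrix(data)
  Z <- model@Z
  if (nrow(Y) != nrow(Z))
    stop("shape mismatch: data has ", nrow(Y), " trials, design has ", nrow(Z))
  a <- drop(MASS::ginv(Z) %*% rowMeans(Y))
  centered <- Y - drop(Z %*% a)
  list(meanCoef = a, centered = centered)
}

#' Marginal log-likelihood of the pattern-component model
#'
#' The mean-removed voxel columns y_p are i.i.d. N(0, V) with
#' V = Z G Z' + I sigma_eps^2, so the log-likelihood is
#' -(NP/2) log(2 pi) - (P/2) log|V| - tr(V^-1 Y Y')/2.
#' Two computational routes are provided: a dense N-dimensional Cholesky of
#' V, and the Woodbury/Sylvester reduction that only factorises the
#' Q-dimensional matrix sigma_eps^2 I + A' Z' Z A (cost independent of P and
#' linear in N). Both agree to near machine precision when V is well
#' conditioned.
#'
#' @param centered mean-removed N x P data matrix (see [removeMean()]).
#' @param model a [ComponentModel-class].
#' @param params a [ComponentParams-class] (theta and noiseVar).
#' @param method "woodbury" (default) or "dense".
#' @return scalar log-likelihood.
#' @export
marginalLogLik <- function(centered, model, params,
                           method = c("woodbury", "dense")) {
  method <- match.arg(method)
  Y <- as.matrix(centered)
  Z <- model@Z
  N <- nrow(Y); P <- ncol(Y); Q <- ncol(Z)
  A <- assembleA(model, params@theta)
  s2 <- params@noiseVar
  if (method == "dense") {
    V <- Z %*% tcrossprod(A) %*% t(Z) + diag(s2, N)
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular covariance: V is not positive definite"))
    quad <- sum(backsolve(ch, Y, transpose = TRUE)^2)
    return(-(N * P / 2) * log(2 * pi) - P * sum(log(diag(ch))) - quad / 2)
  }
  if (s2 <= 0)
    stop("singular covariance: the Woodbury route requires noiseVar > 0")
  K <- crossprod(Z)
  M <- diag(s2, Q) + crossprod(A, K %*% A)
  chM <- tryCatch(chol(M), error = function(e)
    stop("singular covariance: Woodbury core matrix not positive definite"))
  TY <- crossprod(Z, Y)                      # Q x P
  TTt <- tcrossprod(TY)                      # Z' Y Y' Z
  AtTTtA <- crossprod(A, TTt %*% A)
  Minv <- chol2inv(chM)
  trVinvS <- (sum(Y^2) - sum(AtTTtA * Minv)) / s2
  logdetV <- (N - Q) * log(s2) + 2 * sum(log(diag(chM)))
  -(N * P / 2) * log(2 * pi) - (P / 2) * logdetV - trVinvS / 2
}

# Method-of-moments initialisation: G0 from the pseudo-inverse pattern
# estimates, bias-corrected for noise leakage, projected to PSD and onto
# the basis span; sigma0 from the OLS residual variance.
.momInit <- function(Yc, model) {
  Z <- model@Z
  N <- nrow(Yc); P <- ncol(Yc); Q <- ncol(Z)
  Zp <- MASS::ginv(Z)
  U0 <- Zp %*% Yc
  res <- Yc - Z %*% U0
  rk <- qr(Z)$rank
  df <- (N - rk) * P
  s0 <- if (df >= 1) sum(res^2) / df else 0.5 * mean(Yc^2)
  s0 <- max(s0, 1e-8 * mean(Yc^2), .Machine$double.eps)
  G0 <- tcrossprod(U0) / P - s0 * tcrossprod(Zp)
  A0 <- .safeChol(.nearestPSD(G0))
  th0 <- .projectOntoBasis(model, A0)
  scale <- sqrt(mean(Yc^2))
  if (sqrt(sum(th0^2)) < 1e-6 * scale) {
    # degenerate start (e.g. moment estimate collapsed to zero): seed A at a
    # small multiple of the identity so EM can move off the A = 0 fixed point
    th0 <- .projectOntoBasis(model, diag(0.1 * scale + 1e-3, Q))
    if (sqrt(sum(th0^2)) < 1e-10) th0 <- rep(0.1, length(th0))
  }
  list(theta = th0, noiseVar = s0)
}

#' Fit the pattern-component model by expectation-maximisation
#'
#' Maximum-likelihood estimation of the basis weights theta (hence
#' G = A A') and the noise variance, on mean-removed data. The model is
#' reparameterised as y_p = Z A w_p + eps_p with w_p ~ N(0, I_Q), making the
#' complete-data problem linear in theta: the E-step computes the posterior
#' moments of w_p in Q dimensions (per-iteration cost independent of the
#' number of voxels), and the M-step solves an H x H linear system. The
#' marginal log-likelihood is guaranteed non-decreasing across iterations.
#'
#' @param data a [PatternDataset-class] or N x P matrix.
#' @param model a [ComponentModel-class].
#' @param init optional list(theta, noiseVar) overriding the
#'   method-of-moments start.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter iteration cap; reaching it returns \code{converged = FALSE}.
#' @param nRestarts number of EM runs; restarts beyond the first perturb the
#'   starting theta multiplicatively (seeded). The restart with the highest
#'   final log-likelihood is returned.
#' @param seed optional seed for the restart perturbations.
#' @return A [PatternFit-class].
#' @examples
#' m <- buildOneFactorial(3, 5)
#' truth <- rbind(c(1, 0, -0.2), c(0, 1, 0.8), c(-0.2, 0.8, 1))
#' U <- t(chol(truth)) %*% matrix(rnorm(3 * 200), 3)
#' Y <- designMatrix(m) %*% U + matrix(rnorm(15 * 200), 15)
#' fit <- emFit(PatternDataset(Y, rep(c("a", "b", "c"), each = 5)), m)
#' Gmatrix(fit)
#' @export
emFit <- function(data, model, init = NULL, tol = 1e-8, maxIter = 1000L,
                  nRestarts = 1L, seed = NULL) {
  rm0 <- removeMean(data, model)
  Yc <- rm0$centered
  Z <- model@Z
  N <- nrow(Yc); P <- ncol(Yc); Q <- ncol(Z); H <- length(model@basis)

  # P-independent sufficient statistics
  K <- crossprod(Z)
  TY <- crossprod(Z, Yc)            # Q x P
  TTt <- tcrossprod(TY)             # Q x Q
  trYY <- sum(Yc^2)
  KB <- lapply(model@basis, function(B) K %*% B)
  s2floor <- 1e-12 * (trYY / (N * P))
  const <- -(N * P / 2) * log(2 * pi)

  start <- if (is.null(init)) .momInit(Yc, model) else init
  starts <- list(start)
  if (nRestarts > 1L) {
    perturb <- .withSeed(seed, lapply(seq_len(nRestarts - 1L), function(i)
      list(theta = start$theta * exp(stats::rnorm(H, 0, 0.3)) +
             stats::rnorm(H, 0, 0.05 * sqrt(mean(start$theta^2) + 1e-8)),
           noiseVar = start$noiseVar * exp(stats::rnorm(1, 0, 0.2)))))
    starts <- c(starts, perturb)
  }

  runOne <- function(st) {
    theta <- st$theta
    s2 <- max(st$noiseVar, s2floor)
    trace <- numeric(0)
    ll <- -Inf
    converged <- FALSE
    iter <- 0L
    Mmat <- matrix(0, H, H)
    b <- numeric(H)
    repeat {
      iter <- iter + 1L
      A <- assembleA(model, theta)
      M <- diag(s2, Q) + crossprod(A, K %*% A)
      chM <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(chM))
        stop("numerical failure at EM iteration ", iter,
             ": Woodbury core matrix not positive definite")
      Minv <- chol2inv(chM)
      TTtA <- TTt %*% A
      AtTTtA <- crossprod(A, TTtA)
      llNew <- const -
        (P / 2) * ((N - Q) * log(s2) + 2 * sum(log(diag(chM)))) -
        (trYY - sum(AtTTtA * Minv)) / (2 * s2)
      if (!is.finite(llNew))
        stop("numerical failure at EM iteration ", iter,
             ": non-finite log-likelihood")
      trace[iter] <- llNew
      if (iter > 1L && abs(llNew - ll) <= tol * (abs(ll) + 1)) {
        converged <- TRUE
        ll <- llNew
        break
      }
      ll <- llNew
      if (iter >= maxIter) break

      # E-step posterior moments of w (Q-dimensional):
      #   Sigma_w = s2 * Minv;  What = Minv A' Z' Y
      # cross-moment R = Z'Y What' and second moment S2 = What What' + P Sigma_w
      R <- TTtA %*% Minv                                 # Q x Q
      S2 <- Minv %*% AtTTtA %*% Minv + (P * s2) * Minv   # Q x Q
      S2 <- (S2 + t(S2)) / 2
      # M-step: quadratic in theta
      for (g in seq_len(H)) {
        Dg <- KB[[g]] %*% S2
        for (h in seq_len(H)) Mmat[h, g] <- sum(model@basis[[h]] * Dg)
        b[g] <- sum(model@basis[[g]] * R)
      }
      theta <- .symSolve(Mmat, b)
      s2 <- max((trYY - sum(b * theta)) / (N * P), s2floor)
    }
    list(theta = theta, noiseVar = s2, trace = trace, ll = ll,
         iter = iter, converged = converged)
  }

  fits <- lapply(starts, runOne)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]

  G <- assembleG(model, best$theta)
  Uhat <- blupPatterns(G, best$noiseVar, Yc, model)
  new("PatternFit", model = model, theta = best$theta,
      noiseVar = best$noiseVar, G = G, meanCoef = rm0$meanCoef,
      loglikTrace = best$trace, Uhat = Uhat, nIter = best$iter,
      converged = best$converged)
}

#' Best linear unbiased prediction of the hidden patterns
#'
#' Computes the conditional expectation of the pattern components given the
#' (mean-removed) data and the component covariances,
#' U = G Z' (Z G Z' + I sigma_eps^2)^-1 Y. The default route uses the
#' Woodbury identity so only Q-dimensional systems are factorised; the dense
#' route inverts the N x N covariance directly.
#'
#' @param G Q x Q component covariance (or a [PatternFit-class], in which
#'   case \code{noiseVar} and \code{model} are taken from the fit).
#' @param noiseVar noise variance.
#' @param centered mean-removed N x P data matrix.
#' @param model a [ComponentModel-class].
#' @param method "woodbury" or "dense".
#' @return Q x P matrix of BLUP patterns.
#' @export
blupPatterns <- function(G, noiseVar = NULL, centered = NULL, model = NULL,
                         method = c("woodbury", "dense")) {
  method <- match.arg(method)
  if (is(G, "PatternFit")) {
    fit <- G
    if (is.null(model)) model <- fit@model
    if (is.null(noiseVar)) noiseVar <- fit@noiseVar
    G <- fit@G
  }
  Y <- as.matrix(centered)
  Z <- model@Z
  N <- nrow(Y); Q <- ncol(Z)
  if (method == "dense" || noiseVar <= 0) {
    V <- Z %*% G %*% t(Z) + diag(noiseVar, N)
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular covariance: Z G Z' + I noiseVar is rank-deficient"))
    return(G %*% crossprod(Z, chol2inv(ch) %*% Y))
  }
  # G Z'V^-1 Y = (G Z'Y - G Z'Z A Minv A' Z'Y) / s2 with A A' = G
  A <- .safeChol(G)
  K <- crossprod(Z)
  M <- diag(noiseVar, Q) + crossprod(A, K %*% A)
  TY <- crossprod(Z, Y)
  (G %*% TY - (G %*% (K %*% A)) %*% solve(M, crossprod(A, TY))) / noiseVar
}
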