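# shared fixtures and independent oracles used across test files

# random small unconstrained one-factorial instance with known truth
randomInstance <- function(nLevels = 3L, trialsPerLevel = 4L, P = 30L,
                           noiseSd = 0.8) {
  m <- buildOneFactorial(nLevels, trialsPerLevel)
  G <- crossprod(matrix(rnorm(nLevels^2), nLevels))
  U <- t(chol(G + diag(1e-8, nLevels))) %*% matrix(rnorm(nLevels * P), nLevels)
  N <- nLevels * trialsPerLevel
  Y <- designMatrix(m) %*% U + matrix(rnorm(N * P, sd = noiseSd), N)
  list(model = m, G = G,
       data = PatternDataset(Y, rep(paste0("c", seq_len(nLevels)),
                                    each = trialsPerLevel)))
}

# dense per-column multivariate-normal log-density, computed without any
# Woodbury shortcuts (the brute-force oracle for marginalLogLik)
denseLoglikOracle <- function(Yc, model, theta, noiseVar) {
  Z <- designMatrix(model)
  V <- Z %*% assembleG(model, theta) %*% t(Z) + diag(noiseVar, nrow(Z))
  Vi <- solve(V)
  ld <- determinant(V, logarithm = TRUE)$modulus
  s <- 0
  for (p in seq_len(ncol(Yc))) {
    y <- Yc[, p]
    s <- s - 0.5 * (nrow(Z) * log(2 * pi) + ld + drop(y %*% Vi %*% y))
  }
  as.numeric(s)
}

# multi-start BFGS maximisation of the marginal likelihood over
# (theta, log noiseVar): the generic numeric-optimizer oracle for emFit
optimizerOracle <- function(Yc, model, theta0, noiseVar0, nStarts = 4L) {
  H <- length(basisMatrices(model))
  nll <- function(par) {
    tryCatch(-marginalLogLik(Yc, model,
                             ComponentParams(par[seq_len(H)],
                                             exp(par[H + 1L]))),
             error = function(e) 1e10)
  }
  best <- Inf
  for (s in seq_len(nStarts)) {
    p0 <- c(theta0 * exp(rnorm(H, 0, 0.4)) + rnorm(H, 0, 0.05),
            log(noiseVar0) + rnorm(1, 0, 0.3))
    o <- tryCatch(optim(p0, nll, method = "BFGS",
                        control = list(maxit = 1000)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  -best
}

# matched / non-matched mean correlations from a cell x cell matrix with
# "cond:level" dimnames (used for the factorial naive estimators)
crossCondMeans <- function(R) {
  cond <- sub(":.*$", "", rownames(R))
  lev <- sub("^.*:", "", rownames(R))
  conds <- unique(cond)
  i1 <- which(cond == conds[1]); i2 <- which(cond == conds[2])
  matched <- mean(vapply(lev[i1], function(l)
    R[i1[lev[i1] == l], i2[lev[i2] == l]], numeric(1)))
  nm <- R[i1, i2, drop = FALSE]
  c(matched = matched, nonmatched = mean(nm[outer(lev[i1], lev[i2], "!=")]))
}

# corrected matched-level correlation from a factorial fit
correctedMatched <- function(fit) {
  G <- Gmatrix(fit)
  bl <- componentBlocks(fit@model)
  b1 <- bl$level[1]; b2 <- bl$level[5]
  G[b1, b2] / sqrt(G[b1, b1] * G[b2, b2])
}
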