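# internal numerical helpers

# symmetric PSD projection: eigenvalues clipped at zero
.nearestPSD <- function(G) {
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  v <- pmax(e$values, 0)
  G2 <- e$vectors %*% (v * t(e$vectors))
  (G2 + t(G2)) / 2
}

# symmetric matrix square root of a PSD matrix (tolerates rank deficiency)
.psdSqrt <- function(G) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# lower-triangular Cholesky-like factor of a (possibly singular) PSD matrix
.safeChol <- function(G) {
  G <- (G + t(G)) / 2
  ch <- tryCatch(t(chol(G)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  jit <- max(mean(diag(G)), 1) * 1e-10
  for (i in 1:8) {
    ch <- tryCatch(t(chol(G + diag(jit, nrow(G)))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jit <- jit * 100
  }
  # fall back to symmetric square root (not triangular, still G = L L')
  .psdSqrt(G)
}

# solve a symmetric system with pseudo-inverse fallback
.symSolve <- function(M, b) {
  M <- (M + t(M)) / 2
  out <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(out)) out <- MASS::ginv(M) %*% b
  drop(out)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# memoised upper-triangular Cholesky of a squared-exponential spatial
# correlation matrix (re-used across replicates of a scenario)
.cholCache <- new.env(parent = emptyenv())

.sqExpChol <- function(coords, s, jitter = 1e-8) {
  key <- paste(nrow(coords), format(s, digits = 12),
               format(sum(coords * seq_len(length(coords))), digits = 15),
               format(jitter, digits = 6), sep = "|")
  hit <- .cholCache[[key]]
  if (!is.null(hit)) return(hit)
  D <- as.matrix(stats::dist(coords))
  C <- exp(-D^2 / (2 * s^2))
  ch <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
  if (is.null(ch))
    ch <- tryCatch(chol(C + diag(jitter * 1e4, nrow(C))),
                   error = function(e) NULL)
  if (is.null(ch))
    stop("spatial correlation matrix is not positive definite after jitter")
  .cholCache[[key]] <- ch
  ch
}
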