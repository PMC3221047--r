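test_that("mean removal regresses the voxel-averaged trial vector on Z", {
  m1 <- new("ComponentModel", Z = matrix(1, 6, 1), basis = list(diag(1)),
            paramNames = "s", blocks = list(all = 1L), componentNames = "c")
  Y <- matrix(3.7, 6, 10)
  rm1 <- removeMean(Y, m1)
  expect_equal(rm1$meanCoef, 3.7)
  expect_equal(rm1$centered, matrix(0, 6, 10), ignore_attr = TRUE)

  # Z = identity: a holds the per-trial voxel means
  m2 <- buildOneFactorial(6, 1)
  set.seed(4)
  Y <- matrix(rnorm(60), 6)
  rm2 <- removeMean(Y, m2)
  expect_equal(rm2$meanCoef, rowMeans(Y))
  expect_equal(rowMeans(rm2$centered), rep(0, 6))

  # random instance: Z a equals the least-squares fit (normal equations)
  m3 <- buildOneFactorial(3, 4)
  Y <- matrix(rnorm(12 * 20), 12)
  rm3 <- removeMean(Y, m3)
  Z <- designMatrix(m3)
  aLS <- solve(crossprod(Z), crossprod(Z, rowMeans(Y)))
  expect_equal(rm3$meanCoef, drop(aLS))
  expect_equal(drop(MASS::ginv(Z) %*% rowMeans(rm3$centered)), rep(0, 3),
               tolerance = 1e-10)
})

test_that("marginal log-likelihood agrees with closed forms and the dense oracle", {
  m <- buildOneFactorial(3, 2)
  N <- 6; P <- 8
  zero <- ComponentParams(rep(0, 6), 1)
  expect_equal(marginalLogLik(matrix(0, N, P), m, zero),
               -(N * P / 2) * log(2 * pi))
  set.seed(5)
  Y <- matrix(rnorm(N * P), N)
  s2 <- 2.3
  expect_equal(marginalLogLik(Y, m, ComponentParams(rep(0, 6), s2)),
               sum(dnorm(Y, sd = sqrt(s2), log = TRUE)))
  # random instance: Woodbury and dense routes against the brute-force
  # per-column density
  for (i in 1:5) {
    th <- rnorm(6)
    p <- ComponentParams(th, runif(1, 0.5, 2))
    lw <- marginalLogLik(Y, m, p)
    ld <- marginalLogLik(Y, m, p, method = "dense")
    lo <- denseLoglikOracle(Y, m, th, p@noiseVar)
    expect_equal(lw, ld, tolerance = 1e-8)
    expect_equal(lw, lo, tolerance = 1e-8)
  }
})

test_that("EM matches a direct numerical maximisation on small instances", {
  set.seed(6)
  for (i in 1:6) {
    inst <- randomInstance()
    fit <- emFit(inst$data, inst$model)
    Yc <- removeMean(inst$data, inst$model)$centered
    oracle <- optimizerOracle(Yc, inst$model, thetaHat(fit),
                              noiseVariance(fit))
    expect_equal(tail(loglikTrace(fit), 1), oracle, tolerance = 1e-3)
  }
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(7)
  for (i in 1:8) {
    inst <- randomInstance(nLevels = sample(2:4, 1), P = sample(c(20, 60), 1))
    fit <- emFit(inst$data, inst$model)
    d <- diff(loglikTrace(fit))
    expect_true(all(d > -1e-6 * (abs(loglikTrace(fit)[-fit@nIter]) + 1)))
  }
})

test_that("EM recovers the generating covariance and noise at large P", {
  set.seed(8)
  sim <- scenarioOneFactorial(noiseVar = 1, seed = 99, P = 10000L)
  fit <- emFit(sim$data, sim$truth@model)
  Gtrue <- assembleG(sim$truth@model, sim$truth@theta)
  expect_lt(max(abs(Gmatrix(fit) - Gtrue)), 0.15)
  expect_lt(abs(noiseVariance(fit) - 1), 0.02)   # < 2% bias at P = 10^4
})

test_that("restarts and seeding give reproducible fits", {
  set.seed(9)
  inst <- randomInstance()
  f1 <- emFit(inst$data, inst$model, nRestarts = 3L, seed = 11L)
  f2 <- emFit(inst$data, inst$model, nRestarts = 3L, seed = 11L)
  expect_identical(thetaHat(f1), thetaHat(f2))
  expect_identical(loglikTrace(f1), loglikTrace(f2))
})

test_that("BLUP shrinks patterns as the mixed-model formula dictates", {
  m <- buildOneFactorial(4, 1)   # Z = I
  set.seed(10)
  Y <- matrix(rnorm(4 * 12), 4)
  expect_equal(blupPatterns(matrix(0, 4, 4), 1, Y, m), matrix(0, 4, 12),
               ignore_attr = TRUE)
  # G = I, noise 0: no shrinkage (dense route; the system is exactly solvable)
  expect_equal(blupPatterns(diag(4), 0, Y, m, method = "dense"), Y,
               ignore_attr = TRUE)
  # G = I, noise 1: uniform shrinkage by half
  expect_equal(blupPatterns(diag(4), 1, Y, m), Y / 2, ignore_attr = TRUE)
  # noise -> 0 limit approaches the data
  expect_equal(blupPatterns(diag(4), 1e-8, Y, m), Y, tolerance = 1e-6,
               ignore_attr = TRUE)
  # Woodbury and dense routes agree on a general instance
  m2 <- buildOneFactorial(3, 4)
  G <- crossprod(matrix(rnorm(9), 3))
  Y2 <- matrix(rnorm(12 * 10), 12)
  expect_equal(blupPatterns(G, 0.7, Y2, m2),
               blupPatterns(G, 0.7, Y2, m2, method = "dense"),
               tolerance = 1e-8)
})
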