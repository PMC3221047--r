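test_that("sphere enumeration matches brute force at reference radii", {
  expect_equal(nrow(sphereCoords(1)), 7L)     # centre + 6 face neighbours
  expect_equal(nrow(sphereCoords(1.5)), 19L)
  # documented count for the 3.5-voxel sphere used by the spatial scenario
  co <- sphereCoords(3.5)
  expect_equal(nrow(co), 179L)
  expect_true(all(sqrt(rowSums(co^2)) <= 3.5))
  expect_error(sphereCoords(0), "> 0")
})

test_that("smooth fields have the requested spatial correlation", {
  set.seed(18)
  co <- cbind(0:20, 0, 0)
  F <- smoothField(co, 2, 4000)
  # empirical correlation at distance 2 approaches exp(-0.5)
  r2 <- mean(vapply(1:19, function(i) cor(F[, i], F[, i + 2]), numeric(1)))
  expect_lt(abs(r2 - exp(-0.5)), 0.03)
  expect_lt(abs(mean(apply(F, 2, var)) - 1), 0.1)
  # s = 0: independent columns
  F0 <- smoothField(co, 0, 2000)
  expect_lt(abs(mean(vapply(1:20, function(i)
    cor(F0[, i], F0[, i + 1]), numeric(1)))), 0.05)
  # single voxel: a unit-variance scalar stream
  F1 <- smoothField(matrix(0, 1, 3), 2, 5000)
  expect_equal(dim(F1), c(5000L, 1L))
  expect_lt(abs(var(F1[, 1]) - 1), 0.1)
})

test_that("simulated trial covariance converges to Z G Z' + I noiseVar", {
  sim <- scenarioOneFactorial(noiseVar = 2, seed = 19, P = 100000L)
  truth <- sim$truth
  Z <- designMatrix(truth@model)
  V <- Z %*% assembleG(truth@model, truth@theta) %*% t(Z) +
    diag(truth@noiseVar, nrow(Z))
  Y <- patternMatrix(sim$data)
  Vemp <- tcrossprod(Y) / ncol(Y)
  # entrywise 3-SE bound for covariance estimates from P iid columns
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / ncol(Y))
  expect_true(all(abs(Vemp - V) < 3 * se + 1e-8))
})

test_that("scenario draws are bitwise reproducible from their seed", {
  s1 <- scenarioTwoFactorial(4, 0.45, seed = 123)
  s2 <- scenarioTwoFactorial(4, 0.45, seed = 123)
  expect_identical(patternMatrix(s1$data), patternMatrix(s2$data))
  s3 <- scenarioSpatial(1, 1, seed = 55)
  s4 <- scenarioSpatial(1, 1, seed = 55)
  expect_identical(patternMatrix(s3$data), patternMatrix(s4$data))
})

test_that("uninformative voxels scale the matched-level covariance linearly", {
  set.seed(20)
  covAt <- function(fr) {
    sim <- scenarioVoxelSelection(fr, seed = 77, P = 20000L)
    tr <- sim$truth
    idx <- componentBlocks(tr@model)$level
    # empirical covariance between matched-level trial rows via the data:
    # use the generating U by regenerating with the same seed is internal,
    # so measure from condition-mean patterns with noise correction instead
    M <- patternMatrix(sim$data)
    ti <- trialInfo(sim$data)
    m11 <- colMeans(M[ti$condition == "c1:l1", ])
    m21 <- colMeans(M[ti$condition == "c2:l1", ])
    m12 <- colMeans(M[ti$condition == "c1:l2", ])
    # matched minus non-matched cross-covariance isolates gamma_beta
    mean(m11 * m21) - mean(m12 * m21)
  }
  c0 <- covAt(0); c5 <- covAt(0.5)
  expect_lt(abs(c5 / c0 - 0.5), 0.2)
})

test_that("noise-free full-rank designs return the components exactly", {
  m <- buildOneFactorial(4, 1)   # Z = I
  truth <- new("ScenarioTruth", model = m,
               theta = patternComp:::.projectOntoBasis(m, diag(4)),
               noiseVar = 0, targetCorrelations = numeric(),
               spatial = NULL, uninformativeFraction = 0,
               trialInfo = data.frame(condition = paste0("c", 1:4)),
               coords = NULL, nVoxels = 50)
  d <- sampleDataset(truth, seed = 5)
  # Y = Z U = U, so the empirical covariance equals G up to sampling noise
  expect_equal(dim(patternMatrix(d)), c(4L, 50L))
  rm0 <- removeMean(d, m)
  expect_equal(rowMeans(rm0$centered), rep(0, 4), tolerance = 1e-12)
})
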