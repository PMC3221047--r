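test_that("corrected correlations normalise G and flag unstable components", {
  r <- correctedCorrelations(diag(3))
  expect_equal(r@corrected, diag(3), ignore_attr = TRUE)
  r2 <- correctedCorrelations(rbind(c(1, 0.5), c(0.5, 1)))
  expect_equal(r2@corrected[1, 2], 0.5)
  expect_true(all(abs(r2@corrected) <= 1))
  # near-zero variance components are flagged, not clipped
  G <- diag(c(1, 1e-9, 2))
  G[1, 3] <- G[3, 1] <- 0.5
  r3 <- correctedCorrelations(G)
  expect_identical(r3@unstable, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(r3@corrected[2, ])))
  expect_equal(r3@corrected[1, 3], 0.5 / sqrt(2))
})

test_that("expected sample correlation matches its closed form and Monte Carlo", {
  expect_equal(expectedSampleCorr(0.8, 1, 1, 0, 5), 0.8)
  expect_equal(expectedSampleCorr(0.8, 1, 1, 10, 5), 0.8 / 3, tolerance = 1e-12)
  expect_equal(expectedSampleCorr(0, 2, 3, 7, 4), 0)
  # Monte Carlo across a (gamma, noise, n) grid: the mean sample correlation
  # between measured mean patterns matches the formula within 3 SEs
  set.seed(12)
  P <- 150
  for (cfg in list(c(0.8, 10, 5), c(0.5, 2, 3), c(-0.2, 4, 5))) {
    g <- cfg[1]; nv <- cfg[2]; n <- cfg[3]
    L <- t(chol(rbind(c(1, g), c(g, 1))))
    reps <- replicate(3000, {
      U <- L %*% matrix(rnorm(2 * P), 2)
      M <- U + matrix(rnorm(2 * P, sd = sqrt(nv / n)), 2)
      cor(M[1, ], M[2, ])
    })
    expect_lt(abs(mean(reps) - expectedSampleCorr(g, 1, 1, nv, n)),
              3 * sd(reps) / sqrt(3000) + 0.01)
  }
})

test_that("expected cross-condition correlation follows the factorial formulas", {
  expect_equal(expectedCrossConditionCorr(0, 0.5, 2, 2, 1, 1, 0, 5), 0.5 / 3)
  # gamma_beta = 0: matched and non-matched coincide
  expect_equal(expectedCrossConditionCorr(0.3, 0, 2, 2, 1, 1, 4, 5, TRUE),
               expectedCrossConditionCorr(0.3, 0, 2, 2, 1, 1, 4, 5, FALSE))
  # the matched - non-matched difference decreases with noise
  d <- vapply(c(0.5, 2, 4, 8), function(nv)
    expectedCrossConditionCorr(0.3, 0.5, 2, 2, 1, 1, nv, 5, TRUE) -
    expectedCrossConditionCorr(0.3, 0.5, 2, 2, 1, 1, nv, 5, FALSE),
    numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("naive estimators show their documented bias directions", {
  set.seed(13)
  # control-subtraction with a pure-noise control induces positive bias
  reps <- replicate(300, {
    sim <- scenarioCommonActivation(noiseVar = 6,
                                    seed = sample.int(1e6, 1))
    controlSubtractedCorr(sim$data, "control")["s1", "s2"]
  })
  expect_gt(mean(reps), 0 + 2 * sd(reps) / sqrt(300))

  # condition-mean subtraction: identical patterns across levels give the
  # -1/(K-1) residual structure at low noise
  m <- buildFactorial(2, 4, trialsPerCell = 2)
  U <- matrix(rnorm(10 * 400, sd = 1), 10, 400)
  U[3:6, ] <- matrix(rep(U[3, ], 4), 4, byrow = TRUE)   # equal level patterns
  U[7:10, ] <- matrix(rep(U[7, ], 4), 4, byrow = TRUE)
  Y <- designMatrix(m) %*% U + matrix(rnorm(16 * 400, sd = 0.01), 16)
  cond <- rep(c("c1", "c2"), each = 8)
  lev <- rep(rep(paste0("l", 1:4), each = 2), 2)
  pd <- PatternDataset(Y, trialInfo = data.frame(
    condition = paste(cond, lev, sep = ":"), cond = cond, level = lev))
  R <- conditionMeanSubtractedCorr(pd)
  within <- R[1, 2]   # two levels of the same condition
  expect_lt(abs(within - (-1 / 3)), 0.15)
})

test_that("classical MDS reproduces distances and the one-dimensional structure", {
  # any 2-point configuration embeds exactly
  r <- mdsEmbed(rbind(c(1, 0.4), c(0.4, 1)), nDims = 1)
  expect_equal(abs(r$coords[1, 1] - r$coords[2, 1]), 0.6, tolerance = 1e-8)
  # equidistant stimuli: degenerate equal positive eigenvalues
  r2 <- mdsEmbed(diag(3), nDims = 2)
  pos <- r2$eig[r2$eig > 1e-8]
  expect_equal(pos, rep(pos[1], length(pos)), tolerance = 1e-8)
  # the true one-factorial similarity structure is one-dimensional
  Gtrue <- rbind(c(1, 0, -0.2), c(0, 1, 0.8), c(-0.2, 0.8, 1))
  r3 <- mdsEmbed(Gtrue, nDims = 2)
  ev <- sort(r3$eig, decreasing = TRUE)
  expect_lt(abs(ev[2]) / ev[1], 0.05)
  expect_gte(r3$coords[1, 1], 0)   # sign convention
  expect_error(mdsEmbed(rbind(c(1, 0.2), c(0.4, 1))), "symmetric")
})
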