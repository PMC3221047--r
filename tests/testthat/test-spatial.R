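test_that("distance binning matches a brute-force double loop", {
  # two voxels at distance 1 in a single bin
  b <- pairwiseDistanceBins(rbind(c(0, 0, 0), c(1, 0, 0)), c(0.5, 1.5))
  expect_equal(b$counts, 1L)
  expect_equal(b$meanDist, 1)
  # a line of 4 lattice voxels
  line <- cbind(0:3, 0, 0)
  b2 <- pairwiseDistanceBins(line, c(0.5, 1.5, 2.5))
  expect_equal(b2$counts, c(3L, 2L))
  # random coordinates against an O(P^2) loop
  set.seed(14)
  co <- matrix(runif(3 * 25, 0, 4), 25)
  edges <- c(0.3, 1, 2, 3, 5)
  b3 <- pairwiseDistanceBins(co, edges)
  ref <- integer(4)
  for (i in 1:24) for (j in (i + 1):25) {
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    for (k in 1:4) if (d >= edges[k] && d < edges[k + 1]) ref[k] <- ref[k] + 1L
  }
  expect_equal(b3$counts, ref)
  expect_error(pairwiseDistanceBins(co[1, , drop = FALSE], edges), "2 voxels")
  expect_error(pairwiseDistanceBins(co, c(0, 1)), "above 0")
})

test_that("pooled autocorrelation recovers generator smoothness", {
  set.seed(15)
  co <- cbind(rep(1:24, each = 24), rep(1:24, 24), 1)
  edges <- c(0.5, 1.2, 1.6, 2.5, 3.5, 4.5)
  # spatially independent field: near-zero autocorrelation in every bin
  a0 <- componentAcf(matrix(rnorm(6 * nrow(co)), 6), co, edges)
  expect_lt(max(abs(a0$acf)), 0.05)
  # field generated at s = 2: per-bin acf matches exp(-d^2/8) within MC noise
  # (the region is large relative to s, keeping the mean-centring bias small)
  F <- smoothField(co, 2, 60)
  a2 <- componentAcf(F, co, edges)
  expect_lt(max(abs(a2$acf - exp(-a2$binCenters^2 / 8))), 0.06)
  # constant pattern: perfectly smooth, acf 1 everywhere
  ac <- componentAcf(matrix(5, 2, nrow(co)), co, edges)
  expect_equal(ac$acf, rep(1, 5))
})

test_that("squared-exponential fitting inverts exact and degenerate inputs", {
  d <- c(1, 1.4, 2, 3, 4)
  f <- fitSqExp(exp(-d^2 / 8), d, rep(10, 5))
  expect_equal(f$s, 2, tolerance = 1e-4)
  expect_identical(f$flag, "ok")
  fup <- fitSqExp(rep(1, 5), d)
  expect_identical(fup$flag, "upper-bound")
  fneg <- fitSqExp(rep(-0.1, 5), d)
  expect_identical(fneg$flag, "all-negative")
  expect_equal(fneg$s, 0)
  # noisy acf from a simulated s = 1 field recovers s near 1
  set.seed(16)
  co <- cbind(rep(1:14, each = 14), rep(1:14, 14), 1)
  a <- componentAcf(smoothField(co, 1, 40), co, c(0.5, 1.2, 1.6, 2.5, 3.5))
  fs <- fitSqExp(a$acf, a$binCenters, a$pairCounts)
  expect_lt(abs(fs$s - 1), 0.2)
})

test_that("FWHM conversion uses the 2 sqrt(ln 2) constant and is linear", {
  expect_equal(fwhmFromS(2), 3.33, tolerance = 5e-3)
  expect_equal(fwhmFromS(0), 0)
  expect_equal(fwhmFromS(1), 1.6651, tolerance = 1e-4)
  s <- c(0.3, 1.7, 4)
  expect_equal(fwhmFromS(3 * s), 3 * fwhmFromS(s))
  expect_error(fwhmFromS(-1), ">= 0")
})

test_that("two-step smoothness estimation works end to end on a fitted model", {
  set.seed(17)
  sim <- scenarioSpatial(sBeta = 1, sEps = 1, seed = 7)
  fit <- emFit(sim$data, sim$truth@model)
  est <- estimateSmoothness(fit, sim$data)
  expect_named(est, c("condition", "level", "noise"))
  expect_s4_class(est$condition, "SpatialEstimate")
  expect_equal(est$condition@fwhm, 2 * sqrt(log(2)) * est$condition@s)
  expect_lt(abs(est$noise@s - 1), 0.5)
})
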