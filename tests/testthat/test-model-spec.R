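test_that("one-factorial builder produces the indicator design and a full factor", {
  m <- buildOneFactorial(3, 5)
  expect_equal(dim(designMatrix(m)), c(15L, 3L))
  expect_length(basisMatrices(m), 6L)       # K(K+1)/2
  expect_equal(colSums(designMatrix(m)), rep(5, 3))
  m2 <- buildOneFactorial(2, 1)
  expect_equal(designMatrix(m2), diag(2))
  expect_length(basisMatrices(m2), 3L)
  expect_error(buildOneFactorial(1, 5), "invalid design")
})

test_that("common-pattern builder enforces the shared-component structure", {
  m <- buildCommonPattern(3, 5, controlTrials = 5)
  Z <- designMatrix(m)
  expect_equal(dim(Z), c(20L, 4L))
  expect_length(basisMatrices(m), 7L)       # 4 variances + 3 covariances
  # control trials load only the common component
  expect_equal(Z[1:5, ], matrix(rep(c(1, 0, 0, 0), each = 5), 5))
  # common component uncorrelated with stimuli for arbitrary theta
  set.seed(1)
  for (i in 1:10) {
    G <- assembleG(m, rnorm(7))
    expect_equal(unname(G[1, 2:4]), rep(0, 3))
    expect_equal(unname(G[2:4, 1]), rep(0, 3))
  }
  # anchoring drops one degree of freedom and zeroes the named covariance
  ma <- buildCommonPattern(3, 5, controlTrials = 0, anchorPairs = list(c(1, 2)))
  expect_length(basisMatrices(ma), 6L)
  G <- assembleG(ma, rnorm(6))
  expect_equal(G[[2, 3]], 0)
  expect_error(buildCommonPattern(3, 5, controlTrials = 0),
               "unidentifiable")
})

test_that("factorial builder reproduces the constrained two-condition covariance", {
  m <- buildFactorial(2, 4, trialsPerCell = 5)
  expect_equal(ncol(designMatrix(m)), 10L)
  expect_length(basisMatrices(m), 6L)
  mr <- buildFactorial(2, 4, nRuns = 7)
  expect_equal(ncol(designMatrix(mr)), 24L)
  expect_length(basisMatrices(mr), 9L)
  expect_equal(nrow(designMatrix(mr)), 56L)  # 8 cells once per run

  # sparsity pattern at random theta: alpha-beta cross block and
  # non-matched beta pairs are structurally zero
  set.seed(2)
  G <- assembleG(m, rnorm(6))
  expect_equal(unname(G[1:2, 3:10]), matrix(0, 2, 8))
  for (l1 in 1:4) for (l2 in 1:4) {
    if (l1 != l2) {
      expect_equal(G[[2 + l1, 6 + l2]], 0)
      expect_equal(G[[2 + l1, 2 + l2]], 0)
    }
  }
  # equal variances across levels within condition; matched covariance shared
  expect_equal(diag(G)[3:6], rep(G[[3, 3]], 4), ignore_attr = TRUE)
  expect_equal(diag(G)[7:10], rep(G[[7, 7]], 4), ignore_attr = TRUE)
  expect_equal(G[[3, 7]], G[[4, 8]])

  # known parameter point: matched-level corrected correlation 0.5
  th <- c(sqrt(2), 0, sqrt(2), 1, 0.5, sqrt(1 - 0.25))
  G <- assembleG(m, th)
  expect_equal(G[[3, 7]] / sqrt(G[[3, 3]] * G[[7, 7]]), 0.5)
})

test_that("assembleG matches the brute-force double sum and is always PSD", {
  m <- buildFactorial(2, 4)
  set.seed(3)
  for (i in 1:10) {
    th <- rnorm(6, sd = 2)
    G <- assembleG(m, th)
    B <- basisMatrices(m)
    ref <- Reduce(`+`, lapply(seq_along(B), function(h)
      Reduce(`+`, lapply(seq_along(B), function(g)
        th[h] * th[g] * B[[h]] %*% t(B[[g]])))))
    expect_equal(unname(G), ref, tolerance = 1e-12)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * sum(diag(G)))
  }
  expect_equal(unname(assembleG(m, rep(0, 6))), matrix(0, 10, 10))
  m1 <- buildOneFactorial(2, 1)
  expect_equal(unname(assembleG(m1, c(2, 0, 2))), 4 * diag(2))
  expect_error(assembleG(m, rep(0, 5)), "dimension mismatch")
})

test_that("builder designs load each trial once per component role", {
  for (m in list(buildOneFactorial(4, 3), buildCommonPattern(3, 2, 2),
                 buildFactorial(2, 4, 2), buildFactorial(2, 3, nRuns = 4))) {
    Z <- designMatrix(m)
    expect_true(all(Z %in% c(0, 1)))
    # every indicator column sums to that component's trial count
    expect_true(all(colSums(Z) >= 1))
  }
})
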