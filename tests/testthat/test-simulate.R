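test_that("low-dimensional simulator reproduces the target covariance", {
  B <- cbind(c(1, 0.5, -0.8), c(0.7, -1, 0))
  sig <- c(0.9, 1.1, 1)
  spec <- simulationSpec(p = 3, groups = list(g = list(n = 1, x = c(1, 1))),
                         B = B, sigma = sig, nTimepoints = 50000, seed = 31)
  pop <- simulateLowDim(spec)
  y <- tsValues(pop$timeseries[[1]])
  S <- crossprod(scale(y, scale = FALSE)) / nrow(y)
  target <- expectedCovariance(B, c(1, 1), sig)
  expect_lt(norm(S - target, "F") / norm(target, "F"), 0.02)
})

test_that("zero coefficients produce uncorrelated parcels", {
  spec <- simulationSpec(p = 4, groups = list(g = list(n = 1)),
                         B = matrix(0, 4, 1), sigma = rep(1, 4),
                         nTimepoints = 50000, seed = 32)
  y <- tsValues(simulateLowDim(spec)$timeseries[[1]])
  cc <- cor(y)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)
})

test_that("simulation is bitwise reproducible from its seed", {
  spec <- simulationSpec(p = 3, groups = list(a = list(n = 2), b = list(n = 2)),
                         B = cbind(1, c(-1, 0, 1)), sigma = rep(1, 3),
                         nTimepoints = 40, arCoeff = 0.4, seed = 33)
  p1 <- simulateLowDim(spec); p2 <- simulateLowDim(spec)
  for (sid in names(p1$timeseries))
    expect_identical(tsValues(p1$timeseries[[sid]]), tsValues(p2$timeseries[[sid]]))
  s1 <- simulateScatter(diag(3), NULL, groups = list(a = list(n = 3, x2 = 0)),
                        nTimepoints = 20, seed = 34)
  s2 <- simulateScatter(diag(3), NULL, groups = list(a = list(n = 3, x2 = 0)),
                        nTimepoints = 20, seed = 34)
  expect_identical(tsValues(s1$scatters[[2]]), tsValues(s2$scatters[[2]]))
})

test_that("AR(1) filtering preserves marginal variance while adding dependence", {
  spec <- simulationSpec(p = 2, groups = list(g = list(n = 1)),
                         B = matrix(c(1, -1), 2, 1), sigma = c(1, 1),
                         nTimepoints = 20000, arCoeff = 0.5, seed = 35)
  y <- tsValues(simulateLowDim(spec)$timeseries[[1]])
  target <- expectedCovariance(matrix(c(1, -1), 2, 1), 1, c(1, 1))
  expect_lt(max(abs(diag(cov(y)) - diag(target))), 0.1)
  expect_gt(sampleAutocorrelation(y[, 1], 1), 0.3)
  # ESS of AR(1)-filtered output matches the closed-form ratio
  ess <- nEffective(effectiveSampleSize(y))
  expect_lt(abs(ess / 20000 - (1 - 0.5) / (1 + 0.5)) / ((1 - 0.5) / (1 + 0.5)), 0.15)
})

test_that("scatter simulator matches Wishart moments", {
  # E[S] = N * Sigma
  p <- 3; N <- 100
  A <- matrix(c(1, 0.4, 0.2, 0.4, 1.2, 0.3, 0.2, 0.3, 0.9), 3)
  sim <- simulateScatter(A, NULL, groups = list(g = list(n = 2000, x2 = 0)),
                         nTimepoints = N, seed = 36)
  M <- Reduce(`+`, lapply(sim$scatters, tsValues)) / 2000
  expect_lt(norm(M - N * A, "F") / norm(N * A, "F"), 0.05)
  # N = 1: rank-one scatters
  r1 <- simulateScatter(diag(3), NULL, groups = list(g = list(n = 3, x2 = 0)),
                        nTimepoints = 1, seed = 37)
  for (s in r1$scatters)
    expect_identical(qr(tsValues(s))$rank, 1L)
  # diagonal Sigma: off-diagonals average near zero
  dsim <- simulateScatter(diag(2), NULL, groups = list(g = list(n = 800, x2 = 0)),
                          nTimepoints = 50, seed = 38)
  offd <- vapply(dsim$scatters, function(s) tsValues(s)[1, 2], numeric(1))
  expect_lt(abs(mean(offd)) / 50, 0.05)
  expect_error(simulateScatter(diag(2), -2 * diag(2),
                               groups = list(g = list(n = 1, x2 = 1)),
                               nTimepoints = 10, seed = 39),
               "positive definite")
})

test_that("LKJ prior draws behave as the shape parameter dictates", {
  draws <- sampleLKJPrior(2, eta = 1, nDraws = 1000, seed = 40)
  off <- vapply(draws, function(m) m[1, 2], numeric(1))
  # eta = 1 in two dimensions: uniform on (-1, 1)
  expect_gt(stats::ks.test(off, "punif", -1, 1)$p.value, 0.01)
  # large eta concentrates around zero
  off50 <- vapply(sampleLKJPrior(2, eta = 50, nDraws = 1000, seed = 41),
                  function(m) m[1, 2], numeric(1))
  expect_lt(var(off50), var(off))
  # every draw is a valid correlation matrix
  for (m in sampleLKJPrior(5, eta = 0.7, nDraws = 50, seed = 42)) {
    expect_equal(diag(m), rep(1, 5))
    expect_equal(m, t(m))
    expect_gt(min(eigen(m, only.values = TRUE)$values), 0)
  }
})
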