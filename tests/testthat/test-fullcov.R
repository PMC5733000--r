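test_that("the sampling parameterization reproduces the LKJ-plus-flat prior", {
  # analytic gradient of the full-model posterior kernel matches finite
  # differences (covers likelihood, prior change of variables and Jacobians)
  sim <- simulateScatter(diag(3) + 0.3, 0.5 * diag(3),
    groups = list(a = list(n = 8, x2 = 0), b = list(n = 8, x2 = 1)),
    nTimepoints = 30, seed = 3)
  lpg <- hetconn:::fullcovLogpGrad(
    hetconn:::fullcovSuffstats(sim$scatters, sim$design),
    p = 3, eta = 1.4, nuLo = 2, nuHi = 29, twoTerm = TRUE)
  set.seed(601)
  for (r in 1:3) {
    th <- rnorm(13, 0, 0.3)
    num <- vapply(seq_along(th), function(i) {
      e <- 1e-6; tp <- th; tm <- th; tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
      (lpg(tp)$logp - lpg(tm)$logp) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(lpg(th)$grad - num)), 1e-4)
  }
})

test_that("full-model draws always reconstruct valid covariance components", {
  sim <- simulateScatter(diag(4), 0.5 * diag(4) + 0.1,
    groups = list(conv = list(n = 10, x2 = 0), short = list(n = 10, x2 = 1)),
    nTimepoints = 50, seed = 5)
  fit <- fitFullCov(sim$scatters, sim$design, chains = 2, iter = 100,
                    burnin = 100, seed = 6)
  for (term in 1:2) {
    sig <- sigmaDraws(fit, term); om <- omegaDraws(fit, term)
    expect_true(all(sig > 0))
    d <- dim(om)
    for (i in seq(1, d[1], by = 25)) for (c in seq_len(d[2])) {
      O <- om[i, c, , ]
      expect_equal(diag(O), rep(1, 4), tolerance = 1e-10)
      expect_equal(O, t(O))
      expect_true(all(abs(O) <= 1 + 1e-10))
      S <- diag(sig[i, c, ]) %*% O %*% diag(sig[i, c, ])
      expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
    }
  }
  # nu stays inside its prior support (p - 1, N - 1)
  expect_true(all(nuDraws(fit) > 3 & nuDraws(fit) < 49))
})

test_that("a strong group-specific coupling yields high P while null pairs stay low", {
  p <- 5
  Sig2 <- diag(0.5, p); Sig2[1, 2] <- Sig2[2, 1] <- 0.4
  sim <- simulateScatter(diag(p), Sig2,
    groups = list(conv = list(n = 50, x2 = 0), short = list(n = 50, x2 = 1)),
    nTimepoints = 150, seed = 21)
  fit <- fitFullCov(sim$scatters, sim$design, chains = 2, iter = 300,
                    burnin = 300, seed = 8)
  P <- differentialProbability(fit)
  expect_gt(P[1, 2], 0.9)
  # for an exactly-null pair the sign evidence is approximately uniform on
  # (0, 1) -- a single null pair can land high by data noise, so the checks
  # are distributional over the nine null pairs
  nullP <- P[upper.tri(P)][-1]
  expect_lt(min(nullP), 0.5)
  expect_lt(median(nullP), 0.9)
  expect_gt(P[1, 2], max(nullP))
})

test_that("input validation rejects malformed designs and scatters", {
  sim <- simulateScatter(diag(3), NULL, groups = list(a = list(n = 4, x2 = 0)),
                         nTimepoints = 20, seed = 9)
  expect_error(fitFullCov(list(), sim$design, seed = 1), "no scatter")
  expect_error(fitFullCov(sim$scatters, cbind(1, c(-1, 0, 0, 0)), seed = 1),
               "nonnegative")
  expect_error(fitFullCov(sim$scatters, cbind(1, rep(1, 4)), seed = 1),
               "reference")
  expect_error(fitFullCov(sim$scatters, cbind(1, c(0.5, 0, 0, 0)), seed = 1),
               "contrast")
  expect_error(fitFullCov(sim$scatters[1:3], sim$design, seed = 1),
               "design rows")
  mixed <- c(sim$scatters[1:3],
             simulateScatter(diag(2), NULL, groups = list(a = list(n = 1, x2 = 0)),
                             nTimepoints = 20, seed = 10)$scatters)
  expect_error(fitFullCov(mixed, sim$design, seed = 1), "same dimension")
})

test_that("differential probability reflects one-sided posterior mass", {
  # all draws positive -> 1; half positive -> 0; 750/1000 -> 0.5
  n <- 1000
  draws <- array(0, c(n, 2, 2))
  draws[, 1, 2] <- draws[, 2, 1] <- c(rep(1, 750), rep(-1, 250))
  P <- differentialProbability(draws)
  expect_equal(P[1, 2], 0.5)
  draws[, 1, 2] <- draws[, 2, 1] <- 1
  expect_equal(differentialProbability(draws)[1, 2], 1)
  draws[, 1, 2] <- draws[, 2, 1] <- rep(c(1, -1), n / 2)
  expect_equal(differentialProbability(draws)[1, 2], 0)
  # strict inequality: zeros count as not-positive
  draws[, 1, 2] <- draws[, 2, 1] <- c(rep(1, 500), rep(0, 500))
  expect_equal(differentialProbability(draws)[1, 2], 0)
  expect_true(is.na(differentialProbability(draws)[1, 1]))
})
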