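test_that("expected covariance follows the rank-one-plus-diagonal form", {
  expect_equal(expectedCovariance(matrix(c(1, 1), 2, 1), 1, c(1, 1)),
               matrix(c(2, 1, 1, 2), 2))
  # B = 0: pure diagonal
  expect_equal(expectedCovariance(matrix(0, 3, 2), c(1, 1), c(1, 2, 3)),
               diag(c(1, 4, 9)))
  # sign pattern of the contrast column drives off-diagonal signs
  B <- cbind(0, c(-1, 3, 0, 2))
  S <- expectedCovariance(B, c(1, 1), rep(1, 4)) - diag(4)
  expect_lt(S[1, 2], 0)  # parcels 1,2 negatively correlated
  expect_lt(S[1, 4], 0)
  expect_gt(S[2, 4], 0)
  expect_equal(S[3, ], rep(0, 4))  # parcel 3 uncorrelated
  expect_error(expectedCovariance(B, c(1, 1, 1), rep(1, 4)), "length")
})

test_that("expected covariance is symmetric PSD on random instances", {
  set.seed(301)
  for (r in 1:20) {
    p <- sample(2:6, 1); J <- sample(1:3, 1)
    S <- expectedCovariance(matrix(rnorm(p * J), p, J), rnorm(J), runif(p, 0.1, 2))
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
  }
})

test_that("marginal log-likelihood agrees with a dense-covariance oracle", {
  # p = 1, B = 0, y = 0: standard normal density at zero
  expect_equal(marginalLogLik(matrix(0, 1, 1), 1, matrix(1, 1, 1), matrix(0, 1, 1)),
               -0.5 * log(2 * pi))
  set.seed(302)
  for (r in 1:20) {
    p <- sample(1:6, 1); J <- sample(1:3, 1); n <- 5
    B <- matrix(rnorm(p * J), p, J); sig <- runif(p, 0.3, 2)
    X <- matrix(rnorm(n * J), n, J); Y <- matrix(rnorm(n * p), n, p)
    expect_equal(marginalLogLik(B, sig, X, Y), denseMvnLogLik(B, sig, X, Y),
                 tolerance = 1e-8)
  }
  expect_error(marginalLogLik(matrix(NA_real_, 1, 1), 1, matrix(1), matrix(1)),
               "non-finite")
})

test_that("scaling B, sigma and Y by c shifts the log-likelihood by -n*p*log(c)", {
  set.seed(303)
  p <- 4; J <- 2; n <- 7; cc <- 2.7
  B <- matrix(rnorm(p * J), p, J); sig <- runif(p, 0.5, 2)
  X <- cbind(1, rbinom(n, 1, 0.5)); Y <- matrix(rnorm(n * p), n, p)
  expect_equal(marginalLogLik(cc * B, cc * sig, X, cc * Y),
               marginalLogLik(B, sig, X, Y) - n * p * log(cc),
               tolerance = 1e-8)
})

test_that("marginalized likelihood matches the explicit latent-variable model", {
  # Monte Carlo over gamma on a tiny instance: integrating the latent scalar
  # analytically must match brute-force numerical integration
  B <- matrix(c(1, -0.5), 2, 1); sig <- c(0.8, 1.2); x <- 1; y <- c(0.3, -0.7)
  f <- function(g) {
    m <- g * drop(B %*% x)
    exp(sum(dnorm(y, m, sig, log = TRUE))) * dnorm(g)
  }
  numint <- integrate(Vectorize(f), -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(marginalLogLik(B, sig, matrix(x), matrix(y, 1, 2)), log(numint),
               tolerance = 1e-7)
})

test_that("sign alignment recovers reference signs and changes nothing else", {
  set.seed(304)
  iter <- 30; p <- 4; J <- 3
  base <- array(rnorm(iter * p * J, mean = 2), c(iter, 1, p, J))
  patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), J)))
  chains <- nrow(patterns)
  B <- array(NA_real_, c(iter, chains, p, J))
  for (c in seq_len(chains)) for (j in seq_len(J))
    B[, c, , j] <- base[, 1, , j] * patterns[c, j]
  sig <- array(runif(iter * chains * p, 0.5, 2), c(iter, chains, p))
  fit <- new("LowDimFit", B = B, sigma = sig,
             logPost = matrix(0, iter, chains), nChains = as.integer(chains),
             nIterations = as.integer(iter), nBurnin = 0L, seed = 1L,
             aligned = FALSE, parcelLabels = paste0("R", 1:p),
             designNames = paste0("x", 1:J), diagnostics = list())
  al <- alignSigns(fit, reference = 1L)
  expect_true(isAligned(al))
  for (c in seq_len(chains)) for (j in seq_len(J))
    expect_equal(bDraws(al)[, c, , j], base[, 1, , j])
  # |B| and sigma untouched
  expect_equal(abs(bDraws(al)), abs(B))
  expect_equal(sigmaDraws(al), sig)
  # idempotent
  expect_equal(bDraws(alignSigns(al)), bDraws(al))
  # two chains with means B and -B align to identical means
  B2 <- B[, c(1, 2), , , drop = FALSE]
  B2[, 2, , ] <- -B[, 1, , ]
  fit2 <- initialize(fit, B = B2, sigma = sig[, 1:2, , drop = FALSE],
                     logPost = matrix(0, iter, 2), nChains = 2L)
  al2 <- alignSigns(fit2)
  expect_equal(apply(bDraws(al2)[, 1, , ], c(2, 3), mean),
               apply(bDraws(al2)[, 2, , ], c(2, 3), mean))
})

test_that("coefficient summaries classify parcels by interval side", {
  iter <- 400
  set.seed(305)
  draws <- cbind(rnorm(iter, 5, 0.5),    # strictly positive -> set2
                 rnorm(iter, -5, 0.5),   # strictly negative -> set1
                 rnorm(iter, 0, 1))      # symmetric -> undecided
  B <- array(0, c(iter, 1, 3, 2)); B[, 1, , 2] <- draws
  fit <- new("LowDimFit", B = B,
             sigma = array(1, c(iter, 1, 3)), logPost = matrix(0, iter, 1),
             nChains = 1L, nIterations = as.integer(iter), nBurnin = 0L,
             seed = 1L, aligned = TRUE, parcelLabels = paste0("R", 1:3),
             designNames = c("intercept", "contrast"), diagnostics = list())
  summ <- summarizeCoefficients(fit, column = 2, alpha = 0.05, m = 15)
  expect_equal(attr(summ, "quantiles"), c(0.05 / 15, 1 - 0.05 / 15))
  expect_equal(summ$set, c("set2", "set1", "undecided"))
  expect_true(all(summ$lower <= summ$median & summ$median <= summ$upper))
  expect_identical(summ$set == "undecided", summ$lower <= 0 & summ$upper >= 0)
  # unaligned posterior is refused
  expect_error(summarizeCoefficients(initialize(fit, aligned = FALSE)),
               "align")
  # global sign flip leaves the partition intact up to label swap
  flip <- initialize(fit, B = -B)
  sflip <- summarizeCoefficients(flip, column = 2, alpha = 0.05, m = 15)
  expect_equal(tprFdr(coefficientSets(sflip), coefficientSets(summ)),
               c(tpr = 1, fdr = 0))
})

test_that("posterior mean matches the sample second moment when p = J = 1", {
  set.seed(306)
  n <- 600; btrue <- 1.5; strue <- 0.7
  y <- matrix(rnorm(n) * btrue + rnorm(n, 0, strue), n, 1)
  fit <- fitLowDim(y, matrix(1, n, 1), chains = 2, iter = 300, burnin = 300,
                   seed = 21)
  m2 <- mean(drop(bDraws(fit))^2 + drop(sigmaDraws(fit))^2)
  expect_lt(abs(m2 - mean(y^2)) / mean(y^2), 0.1)
})

test_that("null data rarely produces decided parcels at Bonferroni level", {
  # B = 0: no heteroscedastic signal, so every parcel's Bonferroni-corrected
  # contrast interval should cover zero in most replicates
  undecidedAll <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    pop <- makeLowDimPopulation(seed = 400 + r, nConv = 3, nShort = 3, N = 60,
                                B = matrix(0, 3, 2), sigma = rep(1, 3))
    st <- stackObservations(pop$timeseries, pop$subjects, "conv")
    fit <- alignSigns(fitLowDim(st$Y, st$X, chains = 2, iter = 300,
                                burnin = 300, seed = 500 + r))
    summ <- summarizeCoefficients(fit, column = 2, alpha = 0.05)
    if (all(summ$set == "undecided")) undecidedAll <- undecidedAll + 1
  }
  expect_gte(undecidedAll / reps, 0.8)
})

test_that("posterior-predictive covariance matches the fitted model per group", {
  pop <- makeLowDimPopulation(seed = 407, nConv = 4, nShort = 4, N = 120)
  st <- stackObservations(pop$timeseries, pop$subjects, "conv")
  fit <- alignSigns(fitLowDim(st$Y, st$X, chains = 2, iter = 300, burnin = 300,
                              seed = 99))
  Bm <- apply(bDraws(fit), c(3, 4), mean)
  sm <- apply(sigmaDraws(fit), 3, mean)
  set.seed(408)
  for (x2 in c(0, 1)) {
    x <- c(1, x2)
    S <- expectedCovariance(Bm, x, sm)
    n <- 50000
    gamma <- rnorm(n)
    Ysim <- outer(gamma, drop(Bm %*% x)) +
      matrix(rnorm(n * 5), n, 5) %*% diag(sm)
    expect_lt(norm(cov(Ysim) * (n - 1) / n - S, "F") / norm(S, "F"), 0.1)
  }
})

test_that("stacking pairs each subject's rows with its design row", {
  pop <- makeLowDimPopulation(seed = 409, nConv = 2, nShort = 1, N = 50)
  st <- stackObservations(pop$timeseries, pop$subjects, "conv", thinTo = 10)
  expect_identical(nrow(st$Y), 30L)
  expect_identical(nrow(st$X), 30L)
  expect_equal(unname(st$X[, 2]), rep(c(0, 0, 1), each = 10))
  expect_lt(max(abs(colMeans(tsValues(centerColumns(
    pop$timeseries[[1]]))))), 1e-10)
})
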