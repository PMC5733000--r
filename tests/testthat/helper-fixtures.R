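# fixtures built in code: small populations, random evidence matrices, and
# a dense multivariate-normal log-density oracle

strongEffectB <- function() {
  cbind(c(2, 1.5, 1, 1.2, 0.8), c(-1, 1.5, 0, 0.8, -1.2))
}

# power-experiment population: moderate contrast effects so the detection
# curve sits in the partial-power regime (about 50% power at 20-40
# subjects, the operating range of the reference analysis) instead of
# saturating at TPR = 1 for every size
powerEffectB <- function() {
  cbind(c(2, 1.5, 1, 1.2, 0.8), 0.4 * c(-1, 1.5, 0, 0.8, -1.2))
}

makeLowDimPopulation <- function(seed, nConv = 4, nShort = 4, N = 100,
                                 arCoeff = 0, B = strongEffectB(),
                                 sigma = c(1, 1.2, 0.9, 1.1, 1)) {
  spec <- simulationSpec(
    p = nrow(B),
    groups = list(conv = list(n = nConv), short = list(n = nShort)),
    B = B, sigma = sigma, nTimepoints = N, arCoeff = arCoeff, seed = seed)
  simulateLowDim(spec)
}

randomPMatrix <- function(p, seed) {
  set.seed(seed)
  P <- matrix(0, p, p)
  P[upper.tri(P)] <- runif(p * (p - 1) / 2)
  P <- P + t(P)
  diag(P) <- NA_real_
  P
}

# independent dense-covariance log-density oracle for mean-zero normals
denseMvnLogLik <- function(B, sigma, X, Y) {
  p <- nrow(B)
  sum(vapply(seq_len(nrow(Y)), function(i) {
    S <- tcrossprod(B %*% X[i, ]) + diag(rep_len(sigma, p)^2, p)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    -0.5 * (p * log(2 * pi) + ld + drop(t(Y[i, ]) %*% solve(S, Y[i, ])))
  }, numeric(1)))
}

# reconstruct nu * Sigma1 posterior mean from a FullCovFit
posteriorMeanNuSigma1 <- function(fit) {
  sig <- sigmaDraws(fit, 1); om <- omegaDraws(fit, 1); nu <- nuDraws(fit)
  d <- dim(sig); p <- d[3L]
  acc <- matrix(0, p, p)
  for (c in seq_len(d[2L])) for (i in seq_len(d[1L])) {
    acc <- acc + nu[i, c] *
      (diag(sig[i, c, ]) %*% om[i, c, , ] %*% diag(sig[i, c, ]))
  }
  acc / (d[1L] * d[2L])
}
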