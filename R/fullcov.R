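# ---- Cholesky packing helpers -------------------------------------------
# Sigma is sampled through its lower Cholesky factor L (log-diagonal,
# free off-diagonal), column-major lower-triangular order.

packIndex <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

unpackL <- function(v, p, idx) {
  L <- matrix(0, p, p)
  L[idx] <- v
  diag(L) <- exp(diag(L))
  L
}

packGradL <- function(GL, L, p, idx) {
  # GL = d target / d L; log-diagonal chain rule
  diag(GL) <- diag(GL) * diag(L)
  GL[idx]
}

lmvgamma <- function(p, a) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

dlmvgamma <- function(p, a) sum(digamma(a + (1 - seq_len(p)) / 2))

# log LKJ(eta) + flat-sigma prior re-expressed as a density on Sigma:
# (eta-1) log|Sigma| - (eta - 1 + p/2) sum(log Sigma_ii), plus gradient
fullcovPriorSigma <- function(Sigma, SigmaInv, logdet, eta) {
  p <- nrow(Sigma)
  dii <- diag(Sigma)
  logp <- (eta - 1) * (logdet - sum(log(dii))) - (p / 2) * sum(log(dii))
  G <- (eta - 1) * SigmaInv
  diag(G) <- diag(G) - (eta - 1 + p / 2) / dii
  list(logp = logp, grad = G)
}

fullcovSuffstats <- function(scatters, X) {
  p <- nParcels(scatters[[1L]])
  x2 <- X[, 2L]
  out <- lapply(unique(x2), function(v) {
    ii <- which(x2 == v)
    S <- lapply(scatters[ii], tsValues)
    sld <- vapply(S, function(s) {
      d <- determinant(s, logarithm = TRUE)
      if (d$sign <= 0) stop("scatter matrix is singular; Wishart likelihood ",
                            "needs full-rank scatters (N >= p)", call. = FALSE)
      as.numeric(d$modulus)
    }, numeric(1))
    list(x2 = v, K = length(ii), A = Reduce(`+`, S), sld = sum(sld))
  })
  out
}

fullcovLogpGrad <- function(groups, p, eta, nuLo, nuHi, twoTerm) {
  idx <- packIndex(p)
  nL <- nrow(idx)
  jacDiag <- (p - seq_len(p) + 2)          # d(log|Jacobian|)/d u_i
  function(theta) {
    L1 <- unpackL(theta[seq_len(nL)], p, idx)
    if (any(!is.finite(L1))) return(list(logp = -Inf, grad = theta))
    S1 <- tcrossprod(L1)
    if (twoTerm) {
      L2 <- unpackL(theta[nL + seq_len(nL)], p, idx)
      if (any(!is.finite(L2))) return(list(logp = -Inf, grad = theta))
      S2 <- tcrossprod(L2)
    }
    t <- theta[length(theta)]
    s <- 1 / (1 + exp(-t))
    nu <- nuLo + (nuHi - nuLo) * s
    if (!is.finite(nu) || nu <= nuLo || nu >= nuHi)
      return(list(logp = -Inf, grad = theta))
    logp <- 0
    G1 <- matrix(0, p, p); G2 <- matrix(0, p, p); dnu <- 0
    for (g in groups) {
      Sig <- if (g$x2 == 0 || !twoTerm) S1 else S1 + S2
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(list(logp = -Inf, grad = theta))
      Sinv <- chol2inv(ch)
      ld <- 2 * sum(log(diag(ch)))
      logp <- logp + (nu - p - 1) / 2 * g$sld - 0.5 * sum(Sinv * g$A) -
        g$K * (nu * p / 2 * log(2) + nu / 2 * ld + lmvgamma(p, nu / 2))
      Gg <- 0.5 * (Sinv %*% g$A %*% Sinv) - (nu * g$K / 2) * Sinv
      Gg <- symmetrize(Gg)
      G1 <- G1 + Gg
      if (twoTerm && g$x2 != 0) G2 <- G2 + Gg
      dnu <- dnu + g$sld / 2 -
        g$K * (p / 2 * log(2) + ld / 2 + dlmvgamma(p, nu / 2) / 2)
    }
    # priors on Sigma terms (LKJ on correlation + flat scales, transformed)
    ch1 <- chol(S1); pri1 <- fullcovPriorSigma(S1, chol2inv(ch1),
                                               2 * sum(log(diag(ch1))), eta)
    logp <- logp + pri1$logp
    G1 <- G1 + pri1$grad
    if (twoTerm) {
      ch2 <- tryCatch(chol(S2), error = function(e) NULL)
      if (is.null(ch2)) return(list(logp = -Inf, grad = theta))
      pri2 <- fullcovPriorSigma(S2, chol2inv(ch2), 2 * sum(log(diag(ch2))), eta)
      logp <- logp + pri2$logp
      G2 <- G2 + pri2$grad
    }
    # Cholesky + log-diagonal Jacobian
    u1 <- log(diag(L1))
    logp <- logp + sum(jacDiag * u1)
    grad <- numeric(length(theta))
    g1 <- packGradL(2 * (G1 %*% L1), L1, p, idx)
    g1 <- g1 + jacGradVec(p, idx, jacDiag)
    grad[seq_len(nL)] <- g1
    if (twoTerm) {
      u2 <- log(diag(L2))
      logp <- logp + sum(jacDiag * u2)
      g2 <- packGradL(2 * (G2 %*% L2), L2, p, idx)
      g2 <- g2 + jacGradVec(p, idx, jacDiag)
      grad[nL + seq_len(nL)] <- g2
    }
    # nu logistic transform Jacobian
    logp <- logp + log(nuHi - nuLo) + log(s) + log1p(-s)
    grad[length(theta)] <- dnu * (nuHi - nuLo) * s * (1 - s) + (1 - 2 * s)
    list(logp = logp, grad = grad)
  }
}

# gradient of the log-Jacobian with respect to packed coordinates: only the
# diagonal (log-scale) coordinates receive (p - i + 2)
jacGradVec <- function(p, idx, jacDiag) {
  v <- numeric(nrow(idx))
  isDiag <- idx[, 1L] == idx[, 2L]
  v[isDiag] <- jacDiag[idx[isDiag, 1L]]
  v
}

# moment-based initial values: E[S] = nu * Sigma and
# Var(S_ij) = nu * (Sigma_ij^2 + Sigma_ii Sigma_jj)
fullcovInits <- function(scatters, X, p, nChains, seed, nuLo, nuHi, twoTerm) {
  x2 <- X[, 2L]
  Sref <- lapply(scatters[x2 == 0], tsValues)
  Mref <- Reduce(`+`, Sref) / length(Sref)
  if (length(Sref) >= 3L) {
    arr <- simplify2array(Sref)
    V <- apply(arr, c(1L, 2L), stats::var)
    nuMat <- (Mref^2 + tcrossprod(diag(Mref))) / pmax(V, 1e-300)
    nuHat <- stats::median(nuMat[is.finite(nuMat)])
  } else nuHat <- (nuLo + nuHi) / 2
  nuHat <- min(max(nuHat, nuLo + 0.05 * (nuHi - nuLo)),
               nuHi - 0.05 * (nuHi - nuLo))
  Sig1 <- symmetrize(Mref / nuHat)
  Sig1 <- pdProject(Sig1)
  Sig2 <- NULL
  if (twoTerm) {
    Salt <- lapply(scatters[x2 != 0], tsValues)
    Malt <- Reduce(`+`, Salt) / length(Salt)
    Sig2 <- pdProject(symmetrize(Malt / nuHat - Sig1))
  }
  idx <- packIndex(p)
  pack <- function(Sig) {
    L <- t(chol(Sig))
    v <- L[idx]
    isDiag <- idx[, 1L] == idx[, 2L]
    v[isDiag] <- log(diag(L))
    v
  }
  t0 <- stats::qlogis(min(max((nuHat - nuLo) / (nuHi - nuLo), 0.05), 0.95))
  base <- c(pack(Sig1), if (twoTerm) pack(Sig2), t0)
  lapply(seq_len(nChains), function(c) {
    set.seed(deriveSeed(seed, 2000L + c))
    base + stats::rnorm(length(base), 0, 0.02 * pmax(abs(base), 1))
  })
}

# smallest-eigenvalue floor so initial matrices are safely PD
pdProject <- function(S, rel = 1e-3) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  floorv <- rel * max(e$values, 1e-8)
  v <- pmax(e$values, floorv)
  symmetrize(e$vectors %*% (v * t(e$vectors)))
}

#' Fit the full Wishart covariance regression
#'
#' Models per-subject scatter matrices as
#' `S_k ~ Wishart(x_k1 Sigma1 + x_k2 Sigma2, nu)` in the scale
#' parameterization (`E[S_k] = nu * Sigma_xk`), so that scatters built from
#' N independent rows concentrate `nu` near N, and temporal dependence
#' deflates `nu` below N.  Each `Sigma_m = diag(sigma_m) Omega_m
#' diag(sigma_m)` carries an LKJ(eta) prior on the correlation matrix
#' `Omega_m` and a flat prior on the scales; `nu` has a uniform prior on
#' `(p - 1, N - 1)`.  Sampling uses Hamiltonian Monte Carlo on unconstrained
#' Cholesky factors (the LKJ-plus-flat-scale prior is carried over by exact
#' change of variables), which guarantees every reconstructed `Sigma_m`
#' draw is positive definite.
#'
#' @param scatters list of [ScatterMatrix-class] with identical p.
#' @param X K x 2 design matrix: all-ones intercept column, second column in
#'   {0, 1} (0 = reference group).  A constant-zero second column (or a
#'   single-column X) fits the intercept-only model without a
#'   group-difference term.  Designs with negative entries are rejected
#'   since the scale combination must stay positive definite.
#' @param chains,iter,burnin sampler settings (defaults 4, 500, 500).
#' @param seed integer seed; required.
#' @param eta LKJ shape (default 1: uniform over correlation matrices).
#' @param nTimepoints common N for the nu prior's upper bound; defaults to
#'   the minimum N recorded across the scatters (conservative).
#' @param parcelLabels optional labels.
#' @param control optional sampler settings.
#' @return a [FullCovFit-class].
#' @examples
#' sim <- simulateScatter(diag(3), 0.5 * diag(3),
#'   groups = list(conv = list(n = 6, x2 = 0), short = list(n = 6, x2 = 1)),
#'   nTimepoints = 40, seed = 2)
#' fit <- fitFullCov(sim$scatters, sim$design, chains = 2, iter = 100,
#'                   burnin = 100, seed = 3)
#' nuDraws(fit)[1:3, ]
#' @export
fitFullCov <- function(scatters, X, chains = 4, iter = 500, burnin = 500,
                       seed, eta = 1, nTimepoints = NULL,
                       parcelLabels = NULL, control = list()) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (length(scatters) == 0L) stop("no scatter matrices", call. = FALSE)
  stopifnot(all(vapply(scatters, is, logical(1), "ScatterMatrix")))
  p <- nParcels(scatters[[1L]])
  if (!all(vapply(scatters, nParcels, integer(1)) == p))
    stop("all scatter matrices must share the same dimension p", call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != length(scatters))
    stop("design rows must match the number of scatter matrices", call. = FALSE)
  if (any(X < 0))
    stop("design entries must be nonnegative so the Wishart scale stays ",
         "positive definite", call. = FALSE)
  if (any(X[, 1L] != 1)) stop("first design column must be the intercept",
                              call. = FALSE)
  if (ncol(X) == 1L) X <- cbind(X, 0)
  if (ncol(X) != 2L || !all(X[, 2L] %in% c(0, 1)))
    stop("the Wishart model supports J = 2 with a {0,1} contrast column",
         call. = FALSE)
  if (all(X[, 2L] == 1))
    stop("no reference-group subjects: the intercept term is not identified",
         call. = FALSE)
  chains <- assertCount(chains, "chains"); iter <- assertCount(iter, "iter")
  burnin <- assertCount(burnin, "burnin"); seed <- assertCount(seed, "seed", 0L)
  twoTerm <- any(X[, 2L] == 1)
  N <- as.integer(nTimepoints %||% min(vapply(scatters, nTimepoints, integer(1))))
  nuLo <- p - 1; nuHi <- N - 1
  if (nuHi <= nuLo + 1)
    stop("N is too small for the nu prior support (need N - 1 > p)", call. = FALSE)
  groups <- fullcovSuffstats(scatters, X)
  lpg <- fullcovLogpGrad(groups, p, eta, nuLo, nuHi, twoTerm)
  inits <- fullcovInits(scatters, X, p, chains, seed, nuLo, nuHi, twoTerm)
  res <- hmcSample(lpg, inits, nWarmup = burnin, nIter = iter, seed = seed,
                   control = control)
  idx <- packIndex(p); nL <- nrow(idx)
  sig1 <- array(NA_real_, c(iter, chains, p))
  om1 <- array(NA_real_, c(iter, chains, p, p))
  if (twoTerm) {
    sig2 <- array(NA_real_, c(iter, chains, p))
    om2 <- array(NA_real_, c(iter, chains, p, p))
  } else {
    sig2 <- array(numeric(0), c(0L, 0L, 0L))
    om2 <- array(numeric(0), c(0L, 0L, 0L, 0L))
  }
  nu <- matrix(NA_real_, iter, chains)
  for (c in seq_len(chains)) {
    for (i in seq_len(iter)) {
      th <- res$draws[i, c, ]
      L1 <- unpackL(th[seq_len(nL)], p, idx)
      S1 <- tcrossprod(L1)
      sig1[i, c, ] <- sqrt(diag(S1))
      om1[i, c, , ] <- stats::cov2cor(S1)
      if (twoTerm) {
        L2 <- unpackL(th[nL + seq_len(nL)], p, idx)
        S2 <- tcrossprod(L2)
        sig2[i, c, ] <- sqrt(diag(S2))
        om2[i, c, , ] <- stats::cov2cor(S2)
      }
      nu[i, c] <- nuLo + (nuHi - nuLo) / (1 + exp(-th[length(th)]))
    }
  }
  diag <- list(acceptRate = res$accept, divergences = res$divergences,
               stepSize = res$stepSize,
               rhatNu = splitRhat(nu),
               rhatSigma1 = apply(sig1, 3L, splitRhat))
  divRate <- sum(res$divergences) / (chains * iter)
  if (divRate > 0.05)
    diag$warning <- sprintf("divergence rate %.1f%% exceeds 5%%", 100 * divRate)
  new("FullCovFit", sigma1 = sig1, sigma2 = sig2, omega1 = om1, omega2 = om2,
      nu = nu, eta = eta, nTimepoints = N, seed = seed,
      parcelLabels = as.character(parcelLabels %||% defaultParcelLabels(p)),
      diagnostics = diag)
}

#' @rdname accessors
#' @param term 1 for the intercept component, 2 for the group difference.
setMethod("sigmaDraws", "FullCovFit", function(object, term = 1L) {
  if (term == 1L) object@sigma1 else object@sigma2
})

#' @rdname accessors
setMethod("omegaDraws", "FullCovFit", function(object, term = 1L) {
  if (term == 1L) object@omega1 else object@omega2
})

#' @rdname accessors
setMethod("nuDraws", "FullCovFit", function(object) object@nu)

#' @rdname accessors
setMethod("diagnostics", "FullCovFit", function(object) object@diagnostics)

#' @rdname accessors
setMethod("parcelLabels", "FullCovFit", function(object) object@parcelLabels)

#' @rdname accessors
setMethod("nParcels", "FullCovFit", function(object) dim(object@sigma1)[3L])

setMethod("show", "FullCovFit", function(object) {
  d <- dim(object@sigma1)
  cat(sprintf("FullCovFit: p = %d; %d chains x %d draws; eta = %g\n",
              d[3L], d[2L], d[1L], object@eta))
  cat(sprintf("nu prior support (%g, %g); posterior median nu = %.1f\n",
              d[3L] - 1, object@nTimepoints - 1,
              stats::median(object@nu)))
  if (length(object@sigma2) == 0L)
    cat("intercept-only fit (no group-difference term)\n")
})
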