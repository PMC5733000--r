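#' Model-implied covariance of the rank-one covariance regression
#'
#' For the model y = gamma * B x + eps with E(gamma) = 0, Var(gamma) = 1 and
#' Cov(eps) = diag(sigma^2), the covariance of y at design row x is
#' `Sigma_x = (B x)(B x)' + diag(sigma^2)`.
#'
#' @param B p x J coefficient matrix.
#' @param x length-J design row.
#' @param sigma length-p (or scalar) positive noise scale vector.
#' @return symmetric positive-definite p x p matrix.
#' @examples
#' expectedCovariance(matrix(c(1, 1), 2, 1), 1, c(1, 1))
#' @export
expectedCovariance <- function(B, x, sigma) {
  B <- as.matrix(B)
  x <- as.numeric(x)
  if (ncol(B) != length(x))
    stop("length of 'x' must equal the number of columns of 'B'", call. = FALSE)
  p <- nrow(B)
  sigma <- rep_len(as.numeric(sigma), p)
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  m <- drop(B %*% x)
  symmetrize(tcrossprod(m) + diag(sigma^2, p))
}

#' Marginal log-likelihood of the low-dimensional model
#'
#' With Gaussian gamma and eps, integrating the scalar random effect out
#' gives y_i ~ N(0, (B x_i)(B x_i)' + diag(sigma^2)).  Each observation's
#' density is evaluated with rank-one Sherman-Morrison / determinant-lemma
#' identities, so the cost is O(p) per observation rather than O(p^3).
#'
#' @param B p x J coefficient matrix.
#' @param sigma length-p (or scalar) positive noise scales.
#' @param X n x J design matrix (rows matched to rows of `Y`).
#' @param Y n x p observation matrix (one centered p-vector per row).
#' @return the summed log-likelihood (a finite scalar).
#' @export
marginalLogLik <- function(B, sigma, X, Y) {
  B <- as.matrix(B); X <- as.matrix(X); Y <- as.matrix(Y)
  p <- nrow(B)
  if (ncol(X) != ncol(B)) stop("'X' and 'B' disagree on J", call. = FALSE)
  if (ncol(Y) != p) stop("'Y' and 'B' disagree on p", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("'X' and 'Y' disagree on n", call. = FALSE)
  sigma <- rep_len(as.numeric(sigma), p)
  if (any(!is.finite(B)) || any(!is.finite(sigma)) || any(!is.finite(X)) ||
      any(!is.finite(Y))) stop("non-finite input", call. = FALSE)
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  s2 <- sigma^2
  M <- X %*% t(B)                       # n x p, row i = (B x_i)'
  c1 <- 1 + rowSums(M^2 %*% diag(1 / s2, p))    # 1 + m' D^-1 m
  Yd <- sweep(Y, 2L, s2, "/")
  quad <- rowSums(Y * Yd) - rowSums(M * Yd)^2 / c1
  logdet <- sum(log(s2)) + log(c1)
  sum(-0.5 * (p * log(2 * pi) + logdet + quad))
}

# ---- sufficient statistics and posterior kernel --------------------------

# group observations by unique design rows; the likelihood then only needs
# each group's scatter matrix and count
lowdimSuffstats <- function(X, Y) {
  key <- apply(X, 1L, paste, collapse = "\r")
  idx <- split(seq_len(nrow(X)), key)
  groups <- lapply(idx, function(ii) {
    list(x = as.numeric(X[ii[1L], ]),
         n = length(ii),
         S = crossprod(Y[ii, , drop = FALSE]))
  })
  unname(groups)
}

# log-posterior and gradient on theta = c(vec(B), log sigma); flat priors
# on B and on sigma (log-transform Jacobian included); optional weak prior
lowdimLogpGrad <- function(groups, p, J, scalarSigma = FALSE,
                           prior = c("flat", "weak"), bScale = 10) {
  prior <- match.arg(prior)
  nS <- if (scalarSigma) 1L else p
  function(theta) {
    B <- matrix(theta[seq_len(p * J)], p, J)
    ls <- theta[p * J + seq_len(nS)]
    if (any(ls > 40) || any(ls < -40)) return(list(logp = -Inf, grad = theta))
    sigma <- rep_len(exp(ls), p)
    s2 <- sigma^2
    logp <- 0
    gB <- matrix(0, p, J)
    gD <- numeric(p)                       # d logp / d sigma_j^2-ish via G diag
    for (g in groups) {
      m <- drop(B %*% g$x)
      Sig <- tcrossprod(m) + diag(s2, p)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(list(logp = -Inf, grad = theta))
      Sinv <- chol2inv(ch)
      logdet <- 2 * sum(log(diag(ch)))
      SiS <- Sinv %*% g$S
      logp <- logp - 0.5 * (g$n * (p * log(2 * pi) + logdet) + sum(diag(SiS)))
      G <- 0.5 * (SiS %*% Sinv - g$n * Sinv)   # d loglik / d Sigma
      G <- symmetrize(G)
      gB <- gB + 2 * (G %*% m) %*% t(g$x)
      gD <- gD + diag(G)
    }
    gLs <- 2 * s2 * gD                      # chain rule to log sigma
    if (scalarSigma) gLs <- sum(gLs)        # single shared coordinate
    # flat prior on sigma: Jacobian of the log transform
    logp <- logp + sum(ls)
    gLs <- gLs + 1
    if (prior == "weak") {
      logp <- logp - 0.5 * sum(B^2) / bScale^2 - 0.5 * sum((ls / 2.5)^2)
      gB <- gB - B / bScale^2
      gLs <- gLs - ls / 2.5^2
    }
    list(logp = logp, grad = c(as.numeric(gB), gLs))
  }
}

# data-informed initial values: crude rank-one decomposition of each
# group's sample covariance, random column signs per chain
lowdimInits <- function(groups, p, J, nChains, seed, scalarSigma) {
  nTot <- sum(vapply(groups, `[[`, numeric(1), "n"))
  Cpool <- Reduce(`+`, lapply(groups, `[[`, "S")) / nTot
  d0 <- pmax(0.5 * diag(Cpool), 1e-6)
  Xu <- do.call(rbind, lapply(groups, `[[`, "x"))
  Mg <- do.call(rbind, lapply(groups, function(g) {
    C <- g$S / g$n - diag(d0, p)
    e <- eigen(symmetrize(C), symmetric = TRUE)
    drop(e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-3 * mean(d0))))
  }))
  B0 <- if (nrow(Xu) >= J && qr(Xu)$rank == J) t(qr.solve(Xu, Mg)) else
    matrix(0, p, J)
  scale0 <- sqrt(mean(d0))
  lapply(seq_len(nChains), function(c) {
    set.seed(deriveSeed(seed, 1000L + c))
    flips <- sample(c(-1, 1), J, replace = TRUE)
    Bc <- sweep(B0, 2L, flips, "*") + matrix(stats::rnorm(p * J, 0, 0.1 * scale0), p, J)
    lsc <- log(sqrt(d0)) + stats::rnorm(p, 0, 0.1)
    if (scalarSigma) lsc <- mean(lsc)
    c(as.numeric(Bc), lsc)
  })
}

#' Fit the low-dimensional covariance regression by Hamiltonian Monte Carlo
#'
#' Samples the posterior of the p x J coefficient matrix B and the noise
#' scales sigma under the marginal likelihood
#' y_i ~ N(0, (B x_i)(B x_i)' + diag(sigma^2)) with flat priors (uniform on
#' B entries; uniform on sigma_j > 0 via a log transform).  The scalar
#' random effect gamma_i is marginalized analytically rather than sampled.
#'
#' @param Y n x p matrix of stacked (centered, thinned) observation vectors.
#' @param X n x J design matrix, rows matched to rows of `Y`.
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws per chain (default 500).
#' @param burnin warmup/adaptation steps per chain (default 500).
#' @param seed integer seed; required for reproducibility.
#' @param prior "flat" (default, the model's improper priors) or "weak"
#'   (mildly regularizing normals, useful for ill-conditioned stress cases).
#' @param scalarSigma use a single shared noise scale sigma^2 I_p instead of
#'   per-parcel scales (default FALSE).
#' @param parcelLabels,designNames optional dimension names.
#' @param control optional list of sampler settings (see hetconn:::hmcControl).
#' @return an (unaligned) [LowDimFit-class]; apply [alignSigns()] before
#'   summarizing.  Split-Rhat diagnostics for sigma and |B| are in
#'   `diagnostics()`; a divergence rate above 5% is recorded as a warning
#'   string in the diagnostics.
#' @examples
#' sim <- simulateLowDim(simulationSpec(
#'   p = 3, groups = list(a = list(n = 4), b = list(n = 4)),
#'   B = cbind(c(1, 1, 0), c(2, -2, 0)), sigma = rep(1, 3),
#'   nTimepoints = 60, seed = 7))
#' st <- stackObservations(sim$timeseries, sim$subjects, "a")
#' fit <- fitLowDim(st$Y, st$X, chains = 2, iter = 100, burnin = 100, seed = 1)
#' fit <- alignSigns(fit)
#' summarizeCoefficients(fit, column = 2)
#' @export
fitLowDim <- function(Y, X, chains = 4, iter = 500, burnin = 500, seed,
                      prior = c("flat", "weak"), scalarSigma = FALSE,
                      parcelLabels = NULL, designNames = NULL,
                      control = list()) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) == 0L || ncol(Y) == 0L) stop("no observations", call. = FALSE)
  if (nrow(X) != nrow(Y))
    stop("number of design rows must equal number of observation vectors",
         call. = FALSE)
  prior <- match.arg(prior)
  chains <- assertCount(chains, "chains"); iter <- assertCount(iter, "iter")
  burnin <- assertCount(burnin, "burnin"); seed <- assertCount(seed, "seed", min = 0L)
  p <- ncol(Y); J <- ncol(X)
  groups <- lowdimSuffstats(X, Y)
  lpg <- lowdimLogpGrad(groups, p, J, scalarSigma = scalarSigma, prior = prior)
  inits <- lowdimInits(groups, p, J, chains, seed, scalarSigma)
  res <- hmcSample(lpg, inits, nWarmup = burnin, nIter = iter, seed = seed,
                   control = control)
  nS <- if (scalarSigma) 1L else p
  Barr <- array(res$draws[, , seq_len(p * J), drop = FALSE], c(iter, chains, p, J))
  sig <- exp(array(res$draws[, , p * J + seq_len(nS), drop = FALSE],
                   c(iter, chains, nS)))
  if (scalarSigma) sig <- array(rep(sig, p), c(iter, chains, p))
  diag <- list(
    acceptRate = res$accept,
    divergences = res$divergences,
    stepSize = res$stepSize,
    rhatSigma = apply(sig, 3L, function(m) splitRhat(m)),
    rhatAbsB = apply(abs(Barr), c(3L, 4L), function(m) splitRhat(m))
  )
  divRate <- sum(res$divergences) / (chains * iter)
  if (divRate > 0.05)
    diag$warning <- sprintf("divergence rate %.1f%% exceeds 5%%", 100 * divRate)
  new("LowDimFit", B = Barr, sigma = sig, logPost = res$logp,
      nChains = chains, nIterations = as.integer(iter),
      nBurnin = as.integer(burnin), seed = as.integer(seed), aligned = FALSE,
      parcelLabels = as.character(parcelLabels %||% defaultParcelLabels(p)),
      designNames = as.character(designNames %||% colnames(X) %||%
                                   paste0("x", seq_len(J))),
      diagnostics = diag)
}

#' @rdname accessors
#' @param column design column index for draw extraction.
setMethod("bDraws", "LowDimFit", function(object, column = NULL) {
  if (is.null(column)) object@B else object@B[, , , column, drop = FALSE]
})

#' @rdname accessors
setMethod("sigmaDraws", "LowDimFit", function(object, ...) object@sigma)

#' @rdname accessors
setMethod("isAligned", "LowDimFit", function(object) object@aligned)

#' @rdname accessors
setMethod("diagnostics", "LowDimFit", function(object) object@diagnostics)

#' @rdname accessors
setMethod("parcelLabels", "LowDimFit", function(object) object@parcelLabels)

#' @rdname accessors
setMethod("nParcels", "LowDimFit", function(object) dim(object@B)[3L])

setMethod("show", "LowDimFit", function(object) {
  d <- dim(object@B)
  cat(sprintf("LowDimFit: p = %d, J = %d; %d chains x %d draws (burnin %d)\n",
              d[3L], d[4L], object@nChains, object@nIterations, object@nBurnin))
  cat(sprintf("aligned: %s; divergences: %s; mean accept: %.2f\n",
              object@aligned,
              paste(object@diagnostics$divergences, collapse = "/"),
              mean(object@diagnostics$acceptRate)))
})

#' @rdname alignSigns
#' @param reference chain whose column signs define the alignment target.
#' @details B and -B imply the same covariance function, so chains can land
#'   on opposite signs of any column.  Each chain's column j is multiplied
#'   by the sign of the inner product between its mean column and the
#'   reference chain's mean column (the Frobenius-optimal sign); a zero
#'   inner product keeps +1.  |B| entries, sigma draws and likelihood values
#'   are untouched.  Idempotent.
setMethod("alignSigns", "LowDimFit", function(object, reference = 1L) {
  d <- dim(object@B)
  chains <- d[2L]; J <- d[4L]
  if (reference < 1L || reference > chains) stop("bad reference chain index")
  cm <- apply(object@B, c(2L, 3L, 4L), mean)          # chain x p x J
  B <- object@B
  for (c in seq_len(chains)) {
    for (j in seq_len(J)) {
      s <- sum(cm[c, , j] * cm[reference, , j])
      if (s < 0) B[, c, , j] <- -B[, c, , j]
    }
  }
  out <- initialize(object, B = B, aligned = TRUE)
  out@diagnostics$rhatBAligned <- apply(B, c(3L, 4L), function(m) splitRhat(m))
  out
})

#' @rdname summarizeCoefficients
#' @param column design column to summarize (default 2, the group contrast).
#' @param alpha credible level before correction (default 0.05).
#' @param m Bonferroni divisor; defaults to the number of parcels p, giving
#'   interval endpoints at the alpha/m and 1 - alpha/m posterior quantiles
#'   (0.05/15 and 1 - 0.05/15 for the default 15-parcel analysis).
#' @details Parcels whose interval lies entirely below zero are assigned to
#'   set1, entirely above zero to set2; intervals containing zero are
#'   undecided.  Requires an aligned fit.
setMethod("summarizeCoefficients", "LowDimFit",
          function(object, column = 2L, alpha = 0.05, m = NULL) {
  if (!object@aligned)
    stop("posterior must be sign-aligned first; call alignSigns()", call. = FALSE)
  d <- dim(object@B)
  p <- d[3L]
  if (column < 1L || column > d[4L]) stop("bad design column index", call. = FALSE)
  alpha <- assertProb(alpha, "alpha")
  m <- assertCount(m %||% p, "m")
  qlo <- alpha / m; qhi <- 1 - alpha / m
  draws <- matrix(object@B[, , , column], d[1L] * d[2L], p)
  med <- apply(draws, 2L, stats::median)
  lo <- apply(draws, 2L, stats::quantile, probs = qlo, names = FALSE)
  hi <- apply(draws, 2L, stats::quantile, probs = qhi, names = FALSE)
  set <- ifelse(hi < 0, "set1", ifelse(lo > 0, "set2", "undecided"))
  out <- data.frame(parcel = seq_len(p), label = object@parcelLabels,
                    median = med, lower = lo, upper = hi,
                    set = set, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha; attr(out, "m") <- m
  attr(out, "quantiles") <- c(qlo, qhi); attr(out, "column") <- column
  out
})

#' Parcel sets implied by a coefficient summary
#'
#' @param summary the data.frame returned by [summarizeCoefficients()].
#' @return a [ParcelSets-class] with set1/set2 from the interval sides.
#' @export
coefficientSets <- function(summary) {
  parcelSets(set1 = summary$parcel[summary$set == "set1"],
             set2 = summary$parcel[summary$set == "set2"],
             p = nrow(summary))
}

#' Stack per-subject timeseries into model observations
#'
#' Centers (and optionally thins) every subject's series, stacks the rows
#' into one observation matrix and repeats each subject's design row once
#' per retained time point.
#'
#' @param tsList named list of [ParcelTimeseries-class], names = subject ids.
#' @param subjects data.frame with subject_id and group columns.
#' @param referenceGroup group coded 0 in the contrast column.
#' @param thinTo NULL (no thinning) or an integer passed to [thinSeries()]
#'   for every subject (e.g. the study-wide ESS).
#' @return list with `Y` (stacked observations), `X` (matching design rows),
#'   and `design` (the n_subjects x J design matrix).
#' @export
stackObservations <- function(tsList, subjects, referenceGroup, thinTo = NULL) {
  subjects <- validateSubjects(subjects)
  design <- buildDesign(subjects, referenceGroup)
  missing <- setdiff(subjects$subject_id, names(tsList))
  if (length(missing))
    stop("no timeseries for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  blocks <- lapply(seq_len(nrow(subjects)), function(k) {
    ts <- centerColumns(tsList[[subjects$subject_id[k]]])
    if (!is.null(thinTo)) ts <- thinSeries(ts, thinTo)
    v <- tsValues(ts)
    list(Y = v, X = matrix(design[k, ], nrow(v), ncol(design), byrow = TRUE))
  })
  list(Y = do.call(rbind, lapply(blocks, `[[`, "Y")),
       X = do.call(rbind, lapply(blocks, `[[`, "X")),
       design = design)
}
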