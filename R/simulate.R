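#' Specification for a synthetic low-dimensional study
#'
#' Bundles the ground-truth parameters of the rank-one covariance
#' regression: per group, observations are y_t = gamma_t * B x_g + eps_t
#' with gamma_t ~ N(0, 1) and eps_t ~ N(0, diag(sigma^2)), so the per-group
#' covariance is exactly `expectedCovariance(B, x_g, sigma)`.  Optional
#' AR(1) filtering of the gamma sequence and of each noise component (with
#' sqrt(1 - phi^2) innovation scaling) adds temporal dependence without
#' changing marginal variances; this is a test construction for exercising
#' ESS estimation, not part of the model itself.
#'
#' @param p number of parcels.
#' @param groups named list; each element a list with `n` (subjects) and
#'   optionally `x` (length-J design row).  Default design rows follow the
#'   intercept + indicator coding in group order (first group = reference).
#' @param B p x J true coefficient matrix.
#' @param sigma length-p positive true noise scales.
#' @param nTimepoints time points per subject.
#' @param arCoeff AR(1) coefficient in [0, 1).
#' @param seed integer seed; recorded in all outputs.
#' @return a validated list of class "hetconn_sim_spec".
#' @export
simulationSpec <- function(p, groups, B, sigma, nTimepoints, arCoeff = 0, seed) {
  p <- assertCount(p, "p")
  B <- as.matrix(B)
  if (nrow(B) != p) stop("'B' must have p rows", call. = FALSE)
  J <- ncol(B)
  sigma <- rep_len(as.numeric(sigma), p)
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list", call. = FALSE)
  if (abs(arCoeff) >= 1) stop("'arCoeff' must satisfy |phi| < 1", call. = FALSE)
  nTimepoints <- assertCount(nTimepoints, "nTimepoints", min = 2L)
  seed <- assertCount(seed, "seed", min = 0L)
  for (g in seq_along(groups)) {
    if (is.null(groups[[g]]$x)) {
      x <- numeric(J); x[1L] <- 1
      if (J >= 2 && g >= 2) x[min(g, J)] <- 1
      groups[[g]]$x <- x
    }
    if (length(groups[[g]]$x) != J)
      stop("group design row length must equal ncol(B)", call. = FALSE)
    groups[[g]]$n <- assertCount(groups[[g]]$n, "n_subjects")
  }
  structure(list(p = p, groups = groups, B = B, sigma = sigma,
                 nTimepoints = nTimepoints, arCoeff = arCoeff, seed = seed),
            class = "hetconn_sim_spec")
}

#' Ground-truth parcel sets implied by a contrast column
#'
#' Parcels with negative true coefficients form set1, positive set2, zero
#' coefficients are undecided.  (The labels are arbitrary; all set-matching
#' metrics are symmetric in them.)
#'
#' @param b length-p numeric contrast column of the true B.
#' @return a [ParcelSets-class].
#' @export
signPartition <- function(b) {
  parcelSets(set1 = which(b < 0), set2 = which(b > 0), p = length(b))
}

#' Simulate a study population from the low-dimensional model
#'
#' @param spec a [simulationSpec()].
#' @return list with `timeseries` (named list of [ParcelTimeseries-class]),
#'   `subjects` (data.frame subject_id/group/path), `design` (one row per
#'   subject), and `truth` (list with B, sigma, arCoeff, seed and the
#'   [ParcelSets-class] implied by the contrast column, when J >= 2).
#' @examples
#' spec <- simulationSpec(p = 3,
#'   groups = list(conv = list(n = 2), short = list(n = 2)),
#'   B = cbind(1, c(-1, 2, 0)), sigma = rep(1, 3), nTimepoints = 50, seed = 1)
#' pop <- simulateLowDim(spec)
#' names(pop$timeseries)
#' @export
simulateLowDim <- function(spec) {
  stopifnot(inherits(spec, "hetconn_sim_spec"))
  p <- spec$p; N <- spec$nTimepoints; phi <- spec$arCoeff
  tsList <- list(); rows <- list()
  counter <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    m <- drop(spec$B %*% g$x)
    for (k in seq_len(g$n)) {
      counter <- counter + 1L
      sid <- sprintf("%s_%03d", gname, k)
      set.seed(deriveSeed(spec$seed, counter))
      gamma <- ar1Filter(stats::rnorm(N), phi)
      eps <- vapply(seq_len(p), function(j)
        spec$sigma[j] * ar1Filter(stats::rnorm(N), phi), numeric(N))
      y <- outer(gamma, m) + eps
      tsList[[sid]] <- parcelTimeseries(y, subjectId = sid)
      rows[[counter]] <- data.frame(subject_id = sid, group = gname,
                                    path = NA_character_,
                                    stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, rows)
  design <- do.call(rbind, lapply(names(spec$groups), function(gn)
    matrix(spec$groups[[gn]]$x, spec$groups[[gn]]$n,
           ncol(spec$B), byrow = TRUE)))
  truth <- list(B = spec$B, sigma = spec$sigma, arCoeff = phi,
                seed = spec$seed)
  if (ncol(spec$B) >= 2L) truth$sets <- signPartition(spec$B[, 2L])
  list(timeseries = tsList, subjects = subjects, design = design,
       truth = truth)
}

#' Simulate per-subject scatter matrices from the Wishart construction
#'
#' Each subject's N x p timeseries has iid (or AR(1)-filtered) mean-zero
#' normal rows with covariance `x1 * Sigma1 + x2 * Sigma2`; the scatter is
#' S = Y'Y.  With `arCoeff = 0` each S is exactly Wishart(scale = group
#' covariance, df = N).
#'
#' @param Sigma1 p x p positive-definite intercept covariance.
#' @param Sigma2 p x p positive-semidefinite group-difference component.
#' @param groups named list; each element a list with `n` (subjects) and
#'   `x2` (0/1 group indicator; the intercept coefficient is always 1).
#' @param nTimepoints rows N per subject.
#' @param arCoeff AR(1) coefficient over time, in [0, 1).
#' @param seed integer seed.
#' @return list with `scatters` (list of [ScatterMatrix-class]), `subjects`
#'   (data.frame), and `design` (K x 2 matrix).
#' @export
simulateScatter <- function(Sigma1, Sigma2 = NULL, groups, nTimepoints,
                            arCoeff = 0, seed) {
  Sigma1 <- as.matrix(Sigma1)
  p <- nrow(Sigma1)
  if (is.null(Sigma2)) Sigma2 <- matrix(0, p, p)
  Sigma2 <- as.matrix(Sigma2)
  if (!all(dim(Sigma2) == p)) stop("Sigma2 must match Sigma1 in dimension",
                                   call. = FALSE)
  if (abs(arCoeff) >= 1) stop("'arCoeff' must satisfy |phi| < 1", call. = FALSE)
  N <- assertCount(nTimepoints, "nTimepoints")
  seed <- assertCount(seed, "seed", min = 0L)
  scatters <- list(); rows <- list(); xs <- list()
  counter <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    x2 <- g$x2 %||% 0
    Sig <- Sigma1 + x2 * Sigma2
    ch <- tryCatch(chol(Sig), error = function(e)
      stop("group covariance combination is not positive definite",
           call. = FALSE))
    for (k in seq_len(assertCount(g$n, "n_subjects"))) {
      counter <- counter + 1L
      sid <- sprintf("%s_%03d", gname, k)
      set.seed(deriveSeed(seed, 5000L + counter))
      Z <- matrix(stats::rnorm(N * p), N, p)
      if (arCoeff != 0) Z <- apply(Z, 2L, ar1Filter, phi = arCoeff)
      Y <- Z %*% ch
      scatters[[counter]] <- new("ScatterMatrix", values = symmetrize(crossprod(Y)),
                                 nTimepoints = N, subjectId = sid)
      rows[[counter]] <- data.frame(subject_id = sid, group = gname,
                                    path = NA_character_,
                                    stringsAsFactors = FALSE)
      xs[[counter]] <- c(1, x2)
    }
  }
  list(scatters = scatters, subjects = do.call(rbind, rows),
       design = do.call(rbind, xs))
}

#' Draw correlation matrices from the LKJ prior
#'
#' C-vine construction (partial correlations drawn from scaled Beta
#' distributions): at tree level k the canonical partial correlations are
#' `2 Beta(a_k, a_k) - 1` with `a_k = eta + (p - 1 - k)/2`, then converted
#' to plain correlations by the standard recursion.  For p = 2, eta = 1
#' the off-diagonal is uniform on (-1, 1); larger eta concentrates mass
#' around zero, smaller eta pushes it toward the boundary.
#'
#' @param p dimension (>= 2).
#' @param eta shape parameter (> 0); 1 is uniform over correlation matrices.
#' @param nDraws number of matrices.
#' @param seed integer seed.
#' @return list of p x p correlation matrices (unit diagonal, symmetric,
#'   positive definite).
#' @examples
#' draws <- sampleLKJPrior(2, eta = 1, nDraws = 5, seed = 1)
#' draws[[1]]
#' @export
sampleLKJPrior <- function(p, eta, nDraws, seed) {
  p <- assertCount(p, "p", min = 2L)
  if (!is.numeric(eta) || eta <= 0) stop("'eta' must be positive", call. = FALSE)
  nDraws <- assertCount(nDraws, "nDraws")
  set.seed(assertCount(seed, "seed", min = 0L))
  lapply(seq_len(nDraws), function(d) {
    Pc <- matrix(0, p, p)
    for (k in seq_len(p - 1L)) {
      a <- eta + (p - 1L - k) / 2
      for (i in (k + 1L):p) Pc[k, i] <- 2 * stats::rbeta(1L, a, a) - 1
    }
    R <- diag(p)
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        r <- Pc[i, j]
        if (i > 1L) for (l in (i - 1L):1L) {
          r <- r * sqrt((1 - Pc[l, i]^2) * (1 - Pc[l, j]^2)) + Pc[l, i] * Pc[l, j]
        }
        R[i, j] <- R[j, i] <- r
      }
    }
    R
  })
}
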