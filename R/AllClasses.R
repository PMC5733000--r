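#' @import methods
NULL

#' Single-subject parcel timeseries
#'
#' An N x p numeric matrix holding one subject's multivariate timeseries:
#' rows are time points, columns are brain parcels (channels).  Signal units
#' are arbitrary; models in this package only use second moments, so
#' timeseries are column-centered before any covariance step.
#'
#' @slot values numeric matrix, N rows (time) x p columns (parcels).
#' @slot parcelLabels character vector of length p.
#' @slot subjectId single string identifying the subject.
#'
#' @seealso [parcelTimeseries()], [readTimeseries()], [centerColumns()],
#'   [scatterMatrix()]
#' @export
setClass("ParcelTimeseries",
  representation(
    values = "matrix",
    parcelLabels = "character",
    subjectId = "character"
  )
)

setValidity("ParcelTimeseries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L) return("timeseries needs at least 2 time points (N >= 2)")
  if (ncol(v) < 1L) return("timeseries needs at least 1 parcel (p >= 1)")
  if (anyNA(v) || any(!is.finite(v))) return("'values' contains missing or non-finite entries")
  if (length(object@parcelLabels) != ncol(v))
    return("'parcelLabels' length must equal the number of columns")
  if (length(object@subjectId) != 1L) return("'subjectId' must be a single string")
  TRUE
})

#' Per-subject scatter matrix
#'
#' The p x p matrix S = Y'Y of a column-centered timeseries Y, i.e. N times
#' the sample covariance.  Scatter matrices are the "observed" responses of
#' the full Wishart covariance regression.
#'
#' @slot values symmetric positive semidefinite p x p matrix.
#' @slot nTimepoints number of time points N that produced the scatter.
#' @slot subjectId single string.
#'
#' @seealso [scatterMatrix()], [fitFullCov()]
#' @export
setClass("ScatterMatrix",
  representation(
    values = "matrix",
    nTimepoints = "integer",
    subjectId = "character"
  )
)

setValidity("ScatterMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v)) return("'values' must be a square numeric matrix")
  if (anyNA(v)) return("'values' contains missing entries")
  sc <- max(abs(v), 1)
  if (max(abs(v - t(v))) > 1e-10 * sc) return("scatter matrix is not symmetric")
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
    return("scatter matrix is not positive semidefinite")
  if (length(object@nTimepoints) != 1L || object@nTimepoints < 1L)
    return("'nTimepoints' must be a positive integer")
  TRUE
})

#' Effective sample size estimate
#'
#' Result of autocorrelation-based ESS estimation for a multivariate
#' timeseries.  The overall count is the conservative component-wise
#' minimum, floored and clamped to [1, N].
#'
#' @slot nEffective integer overall ESS.
#' @slot perComponentEss numeric vector, one (real-valued) ESS per parcel.
#' @slot maxLagUsed largest autocorrelation lag considered.
#'
#' @seealso [effectiveSampleSize()], [thinSeries()]
#' @export
setClass("EssResult",
  representation(
    nEffective = "integer",
    perComponentEss = "numeric",
    maxLagUsed = "integer"
  )
)

setValidity("EssResult", function(object) {
  if (length(object@nEffective) != 1L || object@nEffective < 1L)
    return("'nEffective' must be a single integer >= 1")
  if (length(object@perComponentEss) < 1L) return("no per-component ESS values")
  TRUE
})

#' Posterior of the low-dimensional covariance regression
#'
#' MCMC draws of the p x J coefficient matrix B and the per-parcel noise
#' scales sigma from the rank-one covariance regression
#' y_i = gamma_i * B x_i + eps_i.  B is only identified up to a per-column
#' sign; [alignSigns()] must be applied before coefficient summaries.
#'
#' @slot B numeric array with dim (iterations, chains, p, J).
#' @slot sigma numeric array with dim (iterations, chains, p).
#' @slot logPost numeric matrix (iterations, chains) of log-posterior values.
#' @slot nChains,nIterations,nBurnin integers describing the run.
#' @slot seed integer seed the run was started from.
#' @slot aligned logical; TRUE once per-column signs are aligned across chains.
#' @slot parcelLabels character vector of length p.
#' @slot designNames character vector of length J.
#' @slot diagnostics list with split-Rhat, acceptance rates, divergence counts.
#'
#' @seealso [fitLowDim()], [alignSigns()], [summarizeCoefficients()]
#' @export
setClass("LowDimFit",
  representation(
    B = "array",
    sigma = "array",
    logPost = "matrix",
    nChains = "integer",
    nIterations = "integer",
    nBurnin = "integer",
    seed = "integer",
    aligned = "logical",
    parcelLabels = "character",
    designNames = "character",
    diagnostics = "list"
  )
)

setValidity("LowDimFit", function(object) {
  if (length(dim(object@B)) != 4L) return("'B' must be a 4-d array (iter, chain, p, J)")
  if (length(dim(object@sigma)) != 3L) return("'sigma' must be a 3-d array (iter, chain, p)")
  if (any(object@sigma <= 0)) return("all sigma draws must be positive")
  if (dim(object@B)[3L] != dim(object@sigma)[3L]) return("p mismatch between B and sigma")
  TRUE
})

#' Posterior of the full Wishart covariance regression
#'
#' MCMC draws from the model S_k ~ Wishart(x_k1 Sigma1 + x_k2 Sigma2, nu)
#' with Sigma_m = diag(sigma_m) Omega_m diag(sigma_m), LKJ(eta) priors on
#' the correlation matrices, flat priors on the scale vectors and a uniform
#' prior on nu over (p - 1, N - 1).
#'
#' @slot sigma1,sigma2 numeric arrays (iterations, chains, p) of scale draws.
#' @slot omega1,omega2 numeric arrays (iterations, chains, p, p) of
#'   correlation-matrix draws.
#' @slot nu numeric matrix (iterations, chains) of degrees-of-freedom draws.
#' @slot eta LKJ shape hyperparameter used.
#' @slot nTimepoints the N used for the upper bound of the nu prior.
#' @slot seed integer seed.
#' @slot parcelLabels character vector of length p.
#' @slot diagnostics list with split-Rhat, acceptance rates, divergence counts.
#'
#' @seealso [fitFullCov()], [differentialProbability()], [fdrThreshold()]
#' @export
setClass("FullCovFit",
  representation(
    sigma1 = "array",
    sigma2 = "array",
    omega1 = "array",
    omega2 = "array",
    nu = "matrix",
    eta = "numeric",
    nTimepoints = "integer",
    seed = "integer",
    parcelLabels = "character",
    diagnostics = "list"
  )
)

setValidity("FullCovFit", function(object) {
  if (length(dim(object@omega1)) != 4L || length(dim(object@omega2)) != 4L)
    return("'omega1'/'omega2' must be 4-d arrays (iter, chain, p, p)")
  if (any(object@sigma1 <= 0) || any(object@sigma2 <= 0))
    return("all scale draws must be positive")
  if (any(object@omega1 < -1 - 1e-8 | object@omega1 > 1 + 1e-8))
    return("'omega1' entries must lie in [-1, 1]")
  TRUE
})

#' Differential-connectivity report
#'
#' Holds the evidence matrix P (P_ij = |2 Prob(Omega2_ij > 0) - 1|), the
#' selection threshold lambda* chosen by grid search to control the
#' posterior expected FDR, the achieved FDR, and the selected parcel pairs.
#' The diagonal of P is undefined (self-connectivity) and stored as NA.
#'
#' @slot P symmetric p x p matrix of sign-evidence probabilities, NA diagonal.
#' @slot lambdaStar selected threshold in [0, 1].
#' @slot fdrAchieved posterior expected FDR of the selection (NA if empty).
#' @slot targetFdr the FDR level that was requested.
#' @slot selectedPairs integer matrix with columns i, j (i < j), one row per
#'   selected pair.
#' @slot parcelLabels character vector of length p.
#'
#' @seealso [fdrThreshold()], [posteriorFDR()]
#' @export
setClass("DifferentialReport",
  representation(
    P = "matrix",
    lambdaStar = "numeric",
    fdrAchieved = "numeric",
    targetFdr = "numeric",
    selectedPairs = "matrix",
    parcelLabels = "character"
  )
)

setValidity("DifferentialReport", function(object) {
  offd <- object@P[upper.tri(object@P)]
  if (length(offd) && (min(offd) < 0 || max(offd) > 1))
    return("off-diagonal entries of P must lie in [0, 1]")
  if (object@lambdaStar < 0 || object@lambdaStar > 1)
    return("'lambdaStar' must lie in [0, 1]")
  if (nrow(object@selectedPairs) > 0 && ncol(object@selectedPairs) != 2L)
    return("'selectedPairs' must have two columns (i, j)")
  TRUE
})

#' Disjoint parcel sets from a coefficient summary
#'
#' Parcels whose Bonferroni-corrected credible interval lies entirely below
#' zero form one set, entirely above zero the other; parcels whose interval
#' covers zero are undecided.  Same-set parcels are positively correlated in
#' the group contrast, cross-set parcels negatively; the set labels
#' themselves carry no sign information.
#'
#' @slot set1,set2 integer vectors of parcel indices (disjoint).
#' @slot p total number of parcels; undecided parcels are the complement.
#'
#' @seealso [summarizeCoefficients()], [tprFdr()]
#' @export
setClass("ParcelSets",
  representation(set1 = "integer", set2 = "integer", p = "integer")
)

setValidity("ParcelSets", function(object) {
  p <- object@p
  if (length(p) != 1L || p < 1L) return("'p' must be a single positive integer")
  idx <- c(object@set1, object@set2)
  if (length(idx) && (min(idx) < 1L || max(idx) > p))
    return("set members must be parcel indices in 1..p")
  if (length(intersect(object@set1, object@set2)) > 0L)
    return("set1 and set2 must be disjoint")
  if (anyDuplicated(object@set1) || anyDuplicated(object@set2))
    return("sets must not contain duplicates")
  TRUE
})
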