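#' Accessors for hetconn S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object from this package.
#' @param ... passed to methods.
#' @return The slot content (matrix, vector or scalar) named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tsValues", function(object) standardGeneric("tsValues"))

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("nParcels", function(object) standardGeneric("nParcels"))

#' @rdname accessors
#' @export
setGeneric("nEffective", function(object) standardGeneric("nEffective"))

#' @rdname accessors
#' @export
setGeneric("perComponentEss", function(object) standardGeneric("perComponentEss"))

#' @rdname accessors
#' @export
setGeneric("bDraws", function(object, ...) standardGeneric("bDraws"))

#' @rdname accessors
#' @export
setGeneric("sigmaDraws", function(object, ...) standardGeneric("sigmaDraws"))

#' @rdname accessors
#' @export
setGeneric("omegaDraws", function(object, ...) standardGeneric("omegaDraws"))

#' @rdname accessors
#' @export
setGeneric("nuDraws", function(object) standardGeneric("nuDraws"))

#' @rdname accessors
#' @export
setGeneric("isAligned", function(object) standardGeneric("isAligned"))

#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname accessors
#' @export
setGeneric("probMatrix", function(object) standardGeneric("probMatrix"))

#' @rdname accessors
#' @export
setGeneric("lambdaStar", function(object) standardGeneric("lambdaStar"))

#' @rdname accessors
#' @export
setGeneric("achievedFdr", function(object) standardGeneric("achievedFdr"))

#' @rdname accessors
#' @export
setGeneric("selectedPairs", function(object) standardGeneric("selectedPairs"))

#' Center each parcel column at mean zero
#'
#' @param object a [ParcelTimeseries-class] (or plain matrix).
#' @return an object of the same class with every column mean-centered.
#' @export
setGeneric("centerColumns", function(object) standardGeneric("centerColumns"))

#' Cross-product scatter matrix of a centered timeseries
#'
#' Computes S = Y'Y after (defensive) column centering.  S is N times the
#' sample covariance and is the per-subject response of the full Wishart
#' model.  With `scale = TRUE` the matrix is divided by N (sample
#' covariance), which is occasionally useful for conditioning; the raw
#' cross-product is the default used by the models.
#'
#' @param object a [ParcelTimeseries-class] or numeric matrix.
#' @param ... further arguments (`scale`, `subjectId`).
#' @return a [ScatterMatrix-class].
#' @export
setGeneric("scatterMatrix", function(object, ...) standardGeneric("scatterMatrix"))

#' Estimate the effective sample size of a timeseries
#'
#' @param object a [ParcelTimeseries-class] or numeric matrix/vector.
#' @param ... further arguments (`maxLag`).
#' @return an [EssResult-class].
#' @export
setGeneric("effectiveSampleSize", function(object, ...) standardGeneric("effectiveSampleSize"))

#' Thin a timeseries to n evenly spaced time points
#'
#' @param object a [ParcelTimeseries-class] or numeric matrix.
#' @param n number of rows to keep, 1 <= n <= N.
#' @return same class as the input with n rows, original order preserved.
#' @export
setGeneric("thinSeries", function(object, n) standardGeneric("thinSeries"))

#' Align posterior signs of the coefficient matrix across chains
#'
#' @param object a [LowDimFit-class].
#' @param ... further arguments (`reference` chain index).
#' @return the fit with per-column chain signs aligned to the reference
#'   chain and the `aligned` flag set.
#' @export
setGeneric("alignSigns", function(object, ...) standardGeneric("alignSigns"))

#' Summarize posterior coefficients into credible intervals and parcel sets
#'
#' @param object an aligned [LowDimFit-class].
#' @param ... further arguments (`column`, `alpha`, `m`).
#' @return a data.frame with one row per parcel (see [LowDimFit-class]).
#' @export
setGeneric("summarizeCoefficients", function(object, ...) standardGeneric("summarizeCoefficients"))

#' Posterior sign-evidence matrix for differential correlations
#'
#' @param object a [FullCovFit-class] or a draws array/matrix of the
#'   group-difference correlation component.
#' @return symmetric matrix of P_ij = |2 Prob(Omega2_ij > 0) - 1| with NA
#'   diagonal.
#' @export
setGeneric("differentialProbability", function(object) standardGeneric("differentialProbability"))
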