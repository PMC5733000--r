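#' @rdname differentialProbability
#' @details `P_ij = |2 Prob(Omega2_ij > 0) - 1|`, with the probability
#'   estimated as the fraction of posterior draws strictly greater than
#'   zero (draws exactly equal to zero count as not-positive; they form a
#'   measure-zero event for the continuous posterior).  P is zero when the
#'   sign of the correlation difference is undecided and approaches one as
#'   the posterior mass concentrates on one sign.  The diagonal is NA:
#'   self-connectivity is undefined.
setMethod("differentialProbability", "FullCovFit", function(object) {
  if (length(object@omega2) == 0L)
    stop("fit has no group-difference component (intercept-only design)",
         call. = FALSE)
  d <- dim(object@omega2)
  draws <- matrix(object@omega2, d[1L] * d[2L], d[3L] * d[4L])
  P <- matrix(abs(2 * colMeans(draws > 0) - 1), d[3L], d[4L])
  P <- symmetrize(P)
  diag(P) <- NA_real_
  dimnames(P) <- list(object@parcelLabels, object@parcelLabels)
  P
})

#' @rdname differentialProbability
setMethod("differentialProbability", "array", function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[2L] != d[3L])
    stop("draws array must have dim (draws, p, p)", call. = FALSE)
  draws <- matrix(object, d[1L], d[2L] * d[3L])
  P <- matrix(abs(2 * colMeans(draws > 0) - 1), d[2L], d[3L])
  P <- symmetrize(P)
  diag(P) <- NA_real_
  P
})

#' Posterior expected false discovery rate of a selection threshold
#'
#' For the evidence matrix P and threshold lambda, the posterior expected
#' FDR is `sum_{i<j} (1 - P_ij) 1(P_ij > lambda) / sum_{i<j} 1(P_ij > lambda)`.
#' Pairs are selected by strict inequality.  When no pair exceeds lambda the
#' FDR is undefined and `NA` is returned (a distinguished "no selection"
#' result rather than a number).
#'
#' @param P symmetric matrix of pairwise probabilities (diagonal ignored).
#' @param lambda threshold in [0, 1).
#' @return the posterior expected FDR, or NA if the selection is empty.
#' @examples
#' P <- matrix(0, 3, 3); P[upper.tri(P)] <- c(0.99, 0.98, 0.6)
#' P <- P + t(P)
#' posteriorFDR(P, 0.9)  # (0.01 + 0.02) / 2
#' @export
posteriorFDR <- function(P, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda >= 1)
    stop("'lambda' must lie in [0, 1)", call. = FALSE)
  vals <- P[upper.tri(P)]
  vals <- vals[!is.na(vals)]
  sel <- vals > lambda
  if (!any(sel)) return(NA_real_)
  mean(1 - vals[sel])
}

#' Choose the FDR-controlling threshold by grid search
#'
#' Scans lambda over a grid from 0 to 0.999 and returns the smallest grid
#' value whose posterior expected FDR is at or below `targetFdr` with a
#' nonempty selection -- the choice that maximizes discoveries subject to
#' the FDR bound, since the selected set only shrinks as lambda grows.  If
#' no grid point qualifies the report is empty with lambda* = 1.
#'
#' @param P symmetric evidence matrix (see [differentialProbability()]).
#' @param targetFdr desired posterior expected FDR in (0, 1).
#' @param gridStep grid resolution (default 0.001).
#' @param parcelLabels optional labels attached to the report.
#' @return a [DifferentialReport-class].
#' @examples
#' P <- matrix(0, 3, 3); P[upper.tri(P)] <- c(0.99, 0.98, 0.6)
#' P <- P + t(P); diag(P) <- NA
#' fdrThreshold(P, 0.05)
#' @export
fdrThreshold <- function(P, targetFdr, gridStep = 0.001, parcelLabels = NULL) {
  targetFdr <- assertProb(targetFdr, "targetFdr")
  grid <- seq(0, 0.999, by = gridStep)
  lambdaStar <- 1
  fdrAchieved <- NA_real_
  for (lam in grid) {
    fdr <- posteriorFDR(P, lam)
    if (!is.na(fdr) && fdr <= targetFdr) {
      lambdaStar <- lam
      fdrAchieved <- fdr
      break
    }
  }
  p <- nrow(P)
  if (lambdaStar < 1) {
    ut <- which(upper.tri(P) & !is.na(P) & P > lambdaStar, arr.ind = TRUE)
    pairs <- cbind(i = ut[, 1L], j = ut[, 2L])
  } else {
    pairs <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  }
  new("DifferentialReport", P = P, lambdaStar = lambdaStar,
      fdrAchieved = fdrAchieved, targetFdr = targetFdr,
      selectedPairs = pairs,
      parcelLabels = as.character(parcelLabels %||% rownames(P) %||%
                                    defaultParcelLabels(p)))
}

#' @rdname accessors
setMethod("probMatrix", "DifferentialReport", function(object) object@P)

#' @rdname accessors
setMethod("lambdaStar", "DifferentialReport", function(object) object@lambdaStar)

#' @rdname accessors
setMethod("achievedFdr", "DifferentialReport", function(object) object@fdrAchieved)

#' @rdname accessors
setMethod("selectedPairs", "DifferentialReport", function(object) object@selectedPairs)

#' @rdname accessors
setMethod("parcelLabels", "DifferentialReport", function(object) object@parcelLabels)

setMethod("show", "DifferentialReport", function(object) {
  cat(sprintf(
    "DifferentialReport: %d pair(s) selected at lambda* = %.3f (target FDR %.3g)\n",
    nrow(object@selectedPairs), object@lambdaStar, object@targetFdr))
  if (!is.na(object@fdrAchieved))
    cat(sprintf("achieved posterior expected FDR: %.4f\n", object@fdrAchieved))
  else cat("empty selection: posterior expected FDR undefined\n")
})

#' Number of distinct parcel pairs
#'
#' `p(p - 1)/2` pairwise connections among p parcels, e.g. 1225 for p = 50.
#'
#' @param p number of parcels, p >= 1.
#' @return integer pair count.
#' @export
pairCount <- function(p) {
  p <- assertCount(p, "p")
  as.integer(p * (p - 1) / 2)
}
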