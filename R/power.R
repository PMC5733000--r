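#' Construct a ParcelSets object
#'
#' @param set1,set2 disjoint integer vectors of parcel indices.
#' @param p total number of parcels.
#' @return a [ParcelSets-class]; undecided parcels are the complement.
#' @export
parcelSets <- function(set1 = integer(0), set2 = integer(0), p) {
  new("ParcelSets", set1 = as.integer(sort(unique(set1))),
      set2 = as.integer(sort(unique(set2))), p = assertCount(p, "p"))
}

#' Undecided parcels of a ParcelSets
#'
#' @param sets a [ParcelSets-class].
#' @return integer vector of parcels in neither set.
#' @export
undecidedParcels <- function(sets) {
  setdiff(seq_len(sets@p), c(sets@set1, sets@set2))
}

setMethod("show", "ParcelSets", function(object) {
  fmt <- function(v) if (length(v)) paste0("R", v, collapse = ", ") else "(empty)"
  cat(sprintf("ParcelSets over %d parcels\n  set1: %s\n  set2: %s\n  undecided: %s\n",
              object@p, fmt(object@set1), fmt(object@set2),
              fmt(undecidedParcels(object))))
})

#' Set-matching true positive count
#'
#' Because parcel-set labels are non-identifiable, predicted sets are
#' compared with the truth under both label matchings:
#' `TP_ijkl = #(pred_i intersect true_j) + #(pred_k intersect true_l)`, and
#' the count is `max(TP_1122, TP_1221)`.
#'
#' @param pred,truth [ParcelSets-class] objects over the same parcels.
#' @return integer count of correctly predicted parcels.
#' @export
truePositiveCount <- function(pred, truth) {
  stopifnot(is(pred, "ParcelSets"), is(truth, "ParcelSets"))
  tp1122 <- length(intersect(pred@set1, truth@set1)) +
    length(intersect(pred@set2, truth@set2))
  tp1221 <- length(intersect(pred@set1, truth@set2)) +
    length(intersect(pred@set2, truth@set1))
  max(tp1122, tp1221)
}

#' Set-matching false positive count
#'
#' `FP_ijkl = #(pred_i \ true_j) + #(pred_k \ true_l)`, minimized over the
#' two label matchings: `min(FP_1122, FP_1221)`.  The max/min are taken
#' independently for TP and FP, which is deliberate even though the two
#' optima may correspond to different matchings.
#'
#' @inheritParams truePositiveCount
#' @return integer count of falsely predicted parcels.
#' @export
falsePositiveCount <- function(pred, truth) {
  stopifnot(is(pred, "ParcelSets"), is(truth, "ParcelSets"))
  fp1122 <- length(setdiff(pred@set1, truth@set1)) +
    length(setdiff(pred@set2, truth@set2))
  fp1221 <- length(setdiff(pred@set1, truth@set2)) +
    length(setdiff(pred@set2, truth@set1))
  min(fp1122, fp1221)
}

#' True positive rate and false discovery rate of a set prediction
#'
#' `TPR = TP / (total true parcels)`; `FDR = FP / (TP + FP)` with the
#' convention FDR = 0 when nothing is predicted.
#'
#' @inheritParams truePositiveCount
#' @return named numeric vector c(tpr = , fdr = ).
#' @examples
#' truth <- parcelSets(c(1, 2, 3), c(4, 5), p = 6)
#' pred <- parcelSets(c(1, 2), c(4, 6), p = 6)
#' tprFdr(pred, truth)  # tpr 0.6, fdr 0.25
#' @export
tprFdr <- function(pred, truth) {
  totalTrue <- length(truth@set1) + length(truth@set2)
  if (totalTrue == 0L)
    stop("truth has no parcels in either set; TPR undefined", call. = FALSE)
  tp <- truePositiveCount(pred, truth)
  fp <- falsePositiveCount(pred, truth)
  c(tpr = tp / totalTrue, fdr = if (tp + fp == 0L) 0 else fp / (tp + fp))
}

# stratified subsample of subject indices preserving the population group
# ratio (non-reference counts rounded to nearest integer)
stratifiedSample <- function(subjects, size, referenceGroup) {
  n <- nrow(subjects)
  if (size > n) stop("sample size exceeds the population", call. = FALSE)
  groups <- unique(subjects$group)
  others <- setdiff(groups, referenceGroup)
  counts <- integer(0)
  for (g in others) {
    ng <- round(size * sum(subjects$group == g) / n)
    ng <- min(max(ng, 1L), sum(subjects$group == g))
    counts[g] <- ng
  }
  counts[referenceGroup] <- size - sum(counts)
  idx <- unlist(lapply(names(counts), function(g) {
    pool <- which(subjects$group == g)
    pool[sample.int(length(pool), counts[g])]
  }), use.names = FALSE)
  sort(idx)
}

#' Repeated-subsampling power analysis of the low-dimensional model
#'
#' For each requested sample size, draws `nReplicates` stratified subsamples
#' of the population (preserving the group ratio), thins every subject to
#' the subsample's study-wide effective sample size, fits the
#' low-dimensional model, sign-aligns it, and classifies parcels into sets
#' with Bonferroni-corrected credible intervals at each significance level
#' alpha.  Predictions are scored against the true parcel sets with the
#' set-matching TPR/FDR metrics and averaged over replicates.
#'
#' The thinning count is the study-wide effective sample size of the full
#' population, computed once before subsampling (the population is thinned
#' the same way the reference analysis of that population would be).
#' Recomputing the minimum-ESS rule inside every subsample would couple the
#' thinning count to the sample size -- one low-ESS subject appears in more
#' large subsamples than small ones -- and can make measured power
#' non-monotone for reasons unrelated to the model.
#'
#' @param tsList named list of [ParcelTimeseries-class] (the population).
#' @param subjects data.frame with subject_id and group.
#' @param truth a [ParcelSets-class] of true parcel sets.  For synthetic
#'   populations use the sign partition of the true contrast column; for
#'   real populations a full-population fit's assignment is a reasonable
#'   convention.
#' @param sampleSizes integer vector of subsample sizes.
#' @param alphas numeric vector of significance levels.
#' @param nReplicates subsamples per size (the reference analysis uses 100;
#'   smaller values are fine for desk-scale experiments).
#' @param seed integer seed.
#' @param referenceGroup group coded 0.
#' @param chains,iter,burnin sampler settings per fit (reduced defaults:
#'   power runs many fits).
#' @param maxLag passed to the ESS step.
#' @param mBonferroni Bonferroni divisor; defaults to p.
#' @return data.frame with columns sample_size, alpha, tpr, fdr,
#'   n_replicates (replicate averages).
#' @export
runPower <- function(tsList, subjects, truth, sampleSizes, alphas,
                     nReplicates = 10, seed, referenceGroup,
                     chains = 2, iter = 250, burnin = 250, maxLag = NULL,
                     mBonferroni = NULL) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(is(truth, "ParcelSets"))
  subjects <- validateSubjects(subjects)
  seed <- assertCount(seed, "seed", min = 0L)
  nReplicates <- assertCount(nReplicates, "nReplicates")
  p <- nParcels(tsList[[1L]])
  grid <- expand.grid(sample_size = sort(sampleSizes), alpha = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  nEff <- studyEss(tsList[subjects$subject_id], maxLag = maxLag)
  acc <- array(0, c(nrow(grid), 2L))
  rep_counter <- 0L
  for (r in seq_len(nReplicates)) {
    for (s in unique(grid$sample_size)) {
      rep_counter <- rep_counter + 1L
      set.seed(deriveSeed(seed, 9000L + rep_counter))
      idx <- stratifiedSample(subjects, s, referenceGroup)
      sub <- subjects[idx, , drop = FALSE]
      subTs <- tsList[sub$subject_id]
      st <- stackObservations(subTs, sub, referenceGroup, thinTo = nEff)
      fit <- fitLowDim(st$Y, st$X, chains = chains, iter = iter,
                       burnin = burnin, seed = deriveSeed(seed, 9500L + rep_counter))
      fit <- alignSigns(fit)
      for (a in alphas) {
        summ <- summarizeCoefficients(fit, column = 2L, alpha = a,
                                      m = mBonferroni %||% p)
        score <- tprFdr(coefficientSets(summ), truth)
        row <- which(grid$sample_size == s & grid$alpha == a)
        acc[row, ] <- acc[row, ] + score
      }
    }
  }
  data.frame(sample_size = grid$sample_size, alpha = grid$alpha,
             tpr = acc[, 1L] / nReplicates, fdr = acc[, 2L] / nReplicates,
             n_replicates = nReplicates)
}
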