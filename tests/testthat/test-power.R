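test_that("set-matching TP and FP counts follow the max/min rule", {
  truth <- parcelSets(c(1, 2, 3), c(4, 5), p = 6)
  pred <- parcelSets(c(1, 2), c(4, 6), p = 6)
  expect_identical(truePositiveCount(pred, truth), 3L)   # max(2+1, 0+0)
  expect_identical(falsePositiveCount(pred, truth), 1L)  # min(0+1, 2+2)
  # identity and label symmetry
  expect_identical(truePositiveCount(truth, truth), 5L)
  swapped <- parcelSets(truth@set2, truth@set1, p = 6)
  expect_identical(truePositiveCount(swapped, truth), 5L)
  expect_identical(falsePositiveCount(truth, truth), 0L)
  # empty prediction
  none <- parcelSets(p = 6)
  expect_identical(falsePositiveCount(none, truth), 0L)
})

test_that("TPR and FDR are ratios of the matched counts", {
  truth <- parcelSets(c(1, 2, 3), c(4, 5), p = 6)
  pred <- parcelSets(c(1, 2), c(4, 6), p = 6)
  expect_equal(tprFdr(pred, truth), c(tpr = 0.6, fdr = 0.25))
  expect_equal(tprFdr(truth, truth), c(tpr = 1, fdr = 0))
  expect_equal(tprFdr(parcelSets(p = 6), truth), c(tpr = 0, fdr = 0))
  expect_error(tprFdr(pred, parcelSets(p = 6)), "undefined")
  # label swap never changes the scores; range always within [0, 1]
  set.seed(501)
  for (r in 1:20) {
    mk <- function() {
      idx <- sample(0:2, 8, replace = TRUE)
      parcelSets(which(idx == 1), which(idx == 2), p = 8)
    }
    t <- mk(); if (length(t@set1) + length(t@set2) == 0) next
    pr <- mk()
    s1 <- tprFdr(pr, t)
    s2 <- tprFdr(parcelSets(pr@set2, pr@set1, p = 8), t)
    expect_equal(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
  }
})

test_that("parcel sets validate disjointness and bounds", {
  expect_error(parcelSets(c(1, 2), c(2, 3), p = 4), "disjoint")
  expect_error(parcelSets(c(0), c(2), p = 4), "1..p")
  expect_identical(undecidedParcels(parcelSets(1, 3, p = 4)), c(2L, 4L))
})

test_that("stratified subsampling preserves the group ratio", {
  subjects <- data.frame(subject_id = sprintf("s%02d", 1:30),
                         group = rep(c("conv", "short"), c(20, 10)))
  set.seed(502)
  idx <- hetconn:::stratifiedSample(subjects, 12, "conv")
  expect_identical(length(idx), 12L)
  expect_identical(sum(subjects$group[idx] == "short"), 4L)
  expect_false(anyDuplicated(idx) > 0)
  expect_error(hetconn:::stratifiedSample(subjects, 31, "conv"), "exceeds")
})

test_that("power analysis scores improve with sample size and level", {
  pop <- makeLowDimPopulation(seed = 503, nConv = 24, nShort = 12, N = 60,
                              arCoeff = 0.3)
  res <- runPower(pop$timeseries, pop$subjects, pop$truth$sets,
                  sampleSizes = c(6, 18), alphas = c(0.01, 0.2),
                  nReplicates = 3, seed = 504, referenceGroup = "conv",
                  chains = 2, iter = 150, burnin = 150)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$tpr >= 0 & res$tpr <= 1))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(res$n_replicates == 3))
  for (a in c(0.01, 0.2)) {
    sub <- res[res$alpha == a, ]
    expect_gte(sub$tpr[sub$sample_size == 18],
               sub$tpr[sub$sample_size == 6] - 1e-9)
  }
  # wider alpha never narrows discovery on the same fits
  for (s in c(6, 18)) {
    sub <- res[res$sample_size == s, ]
    expect_gte(sub$tpr[sub$alpha == 0.2], sub$tpr[sub$alpha == 0.01] - 1e-9)
  }
})

test_that("a full-population single replicate equals one direct fit", {
  pop <- makeLowDimPopulation(seed = 505, nConv = 4, nShort = 2, N = 60)
  res <- runPower(pop$timeseries, pop$subjects, pop$truth$sets,
                  sampleSizes = 6, alphas = 0.05, nReplicates = 1,
                  seed = 506, referenceGroup = "conv",
                  chains = 2, iter = 150, burnin = 150)
  # reproduce the single fit by hand with the same derived seed
  set.seed(hetconn:::deriveSeed(506, 9001L))
  idx <- hetconn:::stratifiedSample(pop$subjects, 6, "conv")
  sub <- pop$subjects[idx, ]
  nEff <- studyEss(pop$timeseries[sub$subject_id])
  st <- stackObservations(pop$timeseries[sub$subject_id], sub, "conv",
                          thinTo = nEff)
  fit <- alignSigns(fitLowDim(st$Y, st$X, chains = 2, iter = 150, burnin = 150,
                              seed = hetconn:::deriveSeed(506, 9501L)))
  summ <- summarizeCoefficients(fit, column = 2, alpha = 0.05, m = 5)
  score <- tprFdr(coefficientSets(summ), pop$truth$sets)
  expect_equal(res$tpr, unname(score["tpr"]))
  expect_equal(res$fdr, unname(score["fdr"]))
})
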