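test_that("cross-validation plans have the stated fold structure", {
  subj <- sprintf("S%03d", 1:170)
  y <- rep(c("control", "patient"), 85)
  plan <- makeCVPlan(subj, y, nOuter = 5, nInner = 4, nPartitions = 10,
                     seed = 3)
  # 170 subjects in 5 folds: every fold holds 34 subjects
  for (p in 1:10)
    expect_equal(unname(tabulate(plan@outerFolds[[p]], 5)), rep(34L, 5))
  # 50 (partition, fold) units; each subject is tested exactly 10 times
  expect_identical(plan@nPartitions * plan@nOuterFolds, 50L)
  # each subject sits in exactly one test fold per partition
  for (p in 1:10)
    expect_length(plan@outerFolds[[p]], 170L)
  # inner folds cover exactly the non-test subjects
  inner <- plan@innerFolds[[1]][[2]]
  expect_setequal(names(inner), subj[plan@outerFolds[[1]] != 2])
  expect_equal(sort(unique(unname(inner))), 1:4)
  # determinism
  plan2 <- makeCVPlan(subj, y, 5, 4, 10, seed = 3)
  expect_identical(plan@outerFolds, plan2@outerFolds)
  expect_identical(plan@innerFolds, plan2@innerFolds)
  expect_error(makeCVPlan(subj[1:3], y[1:3], nOuter = 5), "fewer subjects")
})

test_that("single-feature screening keeps only strictly-above-threshold features", {
  sim <- randomFeatureTable(40, 5, seed = 2)
  X <- sim$X
  X[, 1] <- ifelse(sim$y == "patient", 1, -1) + rnorm(40, sd = 1e-3)
  innerFold <- rep(1:4, 10)
  scr <- screenSingleFeatures(X, sim$y, innerFold)
  expect_equal(unname(scr$accuracy["f001"]), 1)
  expect_true("f001" %in% scr$ids)
  # strict inequality: a perfect feature fails a threshold of 1
  scrStrict <- screenSingleFeatures(X, sim$y, innerFold, threshold = 1)
  expect_false("f001" %in% scrStrict$ids)
})

test_that("label-independent features are screened out at the expected rate", {
  sim <- randomFeatureTable(60, 150, seed = 5)
  innerFold <- rep(1:4, 15)
  scr <- screenSingleFeatures(sim$X, sim$y, innerFold)
  accs <- scr$accuracy
  expect_lt(abs(mean(accs) - 0.5), 0.05)   # chance on average
  expect_lt(length(scr$ids) / 150, 0.25)   # only the lucky tail survives
})

test_that("sequential forward selection is greedy, exhaustive at step 2, deterministic", {
  sim <- randomFeatureTable(32, 5, seed = 7)
  X <- sim$X
  X[, 3] <- ifelse(sim$y == "patient", 2, -2) + rnorm(32, sd = 0.1)
  innerFold <- rep(1:4, 8)
  scr <- screenSingleFeatures(X, sim$y, innerFold, threshold = 0)
  sel <- sfsSelect(X, sim$y, innerFold, scr, maxFeatures = 2)
  expect_identical(sel$sfsOrder[1], "f003")
  expect_equal(sel$innerAccuracyByStep[1], 1)
  # step 2 equals exhaustive search over pairs containing the winner
  pairAcc <- vapply(setdiff(colnames(X), "f003"), function(f) {
    accs <- vapply(1:4, function(v) {
      tr <- innerFold != v
      pred <- fcnetclass:::svmPredict(X[tr, c("f003", f)], sim$y[tr],
                                      X[!tr, c("f003", f)], classifierSpec())
      mean(pred == sim$y[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_identical(sel$sfsOrder[2], names(pairAcc)[which.max(pairAcc)])
  expect_equal(sel$innerAccuracyByStep[2], unname(max(pairAcc)))
  # identical inputs give identical selections
  sel2 <- sfsSelect(X, sim$y, innerFold, scr, maxFeatures = 2)
  expect_identical(sel, sel2)
  expect_error(sfsSelect(X, sim$y, innerFold, list(ids = character(),
                                                   accuracy = numeric())),
               "no screened features")
})

test_that("fold evaluation reports the stated confusion metrics", {
  # hand-checkable toy: separable training, one planted test error
  y <- factor(c(rep("control", 4), rep("patient", 4)),
              levels = c("control", "patient"))
  xTr <- matrix(c(-1, -1.2, -0.8, -1.1, 1, 1.2, 0.8, 1.1), ncol = 1,
                dimnames = list(NULL, "f1"))
  yTe <- factor(c("control", "control", "patient", "patient"),
                levels = c("control", "patient"))
  xTe <- matrix(c(-1, 2, 1, 1.1), ncol = 1, dimnames = list(NULL, "f1"))
  ev <- evaluateFold(xTr, y, xTe, yTe, "f1")
  expect_equal(ev$testAccuracyByStep, 0.75)
  expect_equal(unname(ev$confusionByStep[1, ]), c(2L, 1L, 1L, 0L)) # tp tn fp fn
  # sensitivity 2/2, specificity 1/2 from those counts
  expect_equal(unname(ev$confusionByStep[1, "tp"] /
                 sum(ev$confusionByStep[1, c("tp", "fn")])), 1)
  expect_equal(unname(ev$confusionByStep[1, "tn"] /
                 sum(ev$confusionByStep[1, c("tn", "fp")])), 0.5)

  # degenerate training feature: majority class predicted for everyone
  yMaj <- factor(c(rep("control", 2), rep("patient", 6)),
                 levels = c("control", "patient"))
  xConst <- matrix(rnorm(8, sd = 1e-8), ncol = 1,
                   dimnames = list(NULL, "f1"))
  ev2 <- evaluateFold(xConst, yMaj, xTe, yTe, "f1")
  expect_equal(unname(ev2$confusionByStep[1, c("tp", "tn")]), c(2L, 0L))
  # all predicted patient: sensitivity 1, specificity 0
})

test_that("double CV produces the full trace set and sane aggregates", {
  sim <- randomFeatureTable(20, 8, effect = 3, nInformative = 2, seed = 9)
  plan <- makeCVPlan(sim$subjects, sim$y, nOuter = 5, nInner = 4,
                     nPartitions = 10, seed = 2)
  res <- runDoubleCV(sim$X, sim$y, plan, maxFeatures = 3)
  expect_length(cvTraces(res), 50L)
  expect_identical(nrow(accuracyCurves(res)), 3L)
  expect_true(all(vapply(cvTraces(res), function(tr)
    !anyDuplicated(tr$sfsOrder), logical(1))))
  expect_true(all(vapply(cvTraces(res), function(tr)
    all(tr$innerAccuracyByStep >= 0 & tr$innerAccuracyByStep <= 1),
    logical(1))))
  # strong effect: well above chance
  expect_gt(res@summary$accuracy, 0.8)
  mr <- misclassificationRate(res)
  expect_true(all(mr >= 0 & mr <= 1))
  expect_equal(unname(mr), unname(res@misclassCounts / 10))
  # every subject appears in exactly nPartitions test folds
  appearances <- table(unlist(lapply(cvTraces(res), `[[`, "testSubjects")))
  expect_true(all(appearances == 10))
})

test_that("score correlation and d-prime match their formulas", {
  mr <- c(0.1, 0.4, 0.3, 0.8, 0.6, 0.2)
  expect_equal(correlateScores(mr, mr)$r, 1)
  expect_equal(correlateScores(mr, -mr)$r, -1)
  sc <- c(10, 30, 25, 60, 50, 18)
  out <- correlateScores(mr, sc)
  num <- sum((mr - mean(mr)) * (sc - mean(sc)))
  den <- sqrt(sum((mr - mean(mr))^2) * sum((sc - mean(sc))^2))
  expect_equal(out$r, num / den, tolerance = 1e-12)
  expect_equal(out$pValue, stats::cor.test(mr, sc)$p.value)
  expect_error(correlateScores(rep(0.2, 5), sc[1:5]), "variance")

  y <- factor(rep(c("control", "patient"), each = 4),
              levels = c("control", "patient"))
  expect_equal(dPrime(c(1, 2, 3, 4, 1, 2, 3, 4), y)$dprime, 0)
  v <- c(0, 2, 0, 2, 2, 4, 2, 4)   # gap 2 equals the common sd
  sdc <- stats::sd(v[1:4])
  expect_equal(dPrime(v, y)$dprime, 2 / sdc)
  hand <- (mean(v[5:8]) - mean(v[1:4])) /
    sqrt((stats::var(v[5:8]) + stats::var(v[1:4])) / 2)
  expect_equal(dPrime(v, y)$dprime, hand)
  expect_error(dPrime(rep(1, 8), y), "variance")
})

test_that("comparator selectors rank features as specified", {
  sim <- randomFeatureTable(40, 20, seed = 11)
  X <- sim$X
  X[, 5] <- ifelse(sim$y == "patient", 1.5, -1.5) + rnorm(40, sd = 0.2)
  innerFold <- rep(1:4, 10)
  scr <- screenSingleFeatures(X, sim$y, innerFold, threshold = 0)
  ind <- selectIndependent(scr, k = 5)
  expect_identical(ind[1], "f005")
  # ranking matches the screen accuracies
  expect_identical(ind, scr$ids[order(-scr$accuracy[scr$ids],
                                      seq_along(scr$ids))][1:5])

  lda <- selectLDA(X, sim$y, k = 5)
  expect_identical(lda[1], "f005")
  # two-feature case: weights match the closed-form pooled-scatter solution
  X2 <- X[, c(5, 9)]
  g0 <- X2[sim$y == "control", ]; g1 <- X2[sim$y == "patient", ]
  Sw <- crossprod(scale(g0, scale = FALSE)) + crossprod(scale(g1, scale = FALSE))
  w <- solve(Sw, colMeans(g1) - colMeans(g0))
  expect_identical(selectLDA(X2, sim$y, k = 2),
                   colnames(X2)[order(-abs(w))])
  # more features than subjects: pseudo-inverse keeps this defined
  wide <- randomFeatureTable(10, 40, seed = 12)
  expect_length(selectLDA(wide$X, wide$y, k = 40), 40L)
})

test_that("adaboost fits separable data and keeps weights normalised", {
  sim <- randomFeatureTable(30, 3, seed = 13)
  X <- sim$X
  X[, 1] <- ifelse(sim$y == "patient", 2, -2)
  fit <- adaboostClassify(X, sim$y, X, nWeak = 10, seed = 1)
  expect_equal(mean(fit$predictions == sim$y), 1)
  expect_true(all(abs(fit$weightSums - 1) < 1e-12))
  expect_true(all(fit$alphas > 0))
  fit2 <- adaboostClassify(X, sim$y, X, nWeak = 10, seed = 1)
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("cross-session evaluation freezes selection and model on session 1", {
  sim <- randomFeatureTable(40, 12, effect = 2.5, nInformative = 2, seed = 15)
  same <- crossSessionEval(sim$X, sim$y, sim$X, maxFeatures = 3, seed = 4)
  expect_gt(same$accuracy, 0.85)
  # destroying the subject-feature pairing of session 2 drops to chance
  set.seed(16)
  shuffled <- sim$X[sample(nrow(sim$X)), ]
  rownames(shuffled) <- rownames(sim$X)
  mixed <- crossSessionEval(sim$X, sim$y, shuffled, maxFeatures = 3, seed = 4)
  expect_lt(mixed$accuracy, 0.75)
  expect_gt(same$accuracy, mixed$accuracy)
  expect_error(crossSessionEval(sim$X, sim$y, sim$X[c(2, 1, 3:40), ]),
               "same subjects")
})

test_that("session-state variability degrades cross-session accuracy", {
  sessionAccuracy <- function(stateSd, seed) {
    cfg <- syntheticConfig(gridDims = c(4, 4, 2), nTrueRegions = 4,
                           nControls = 10, nPatients = 10, nTimepoints = 100,
                           basePairs = data.frame(regionA = 1, regionB = 2,
                                                  value = 0.6),
                           plantedEffects = data.frame(regionA = 1,
                                                       regionB = 2,
                                                       delta = -0.5),
                           voxelNoiseSd = 0.3, sessionStateSd = stateSd,
                           seed = seed)
    sim <- generateCohort(cfg)
    atlas <- new("VoxelAtlas", voxelRegionLabels = regionLabels(sim$truth),
                 nRegions = 4L, coords = voxelCoords(sim$truth))
    featsOf <- function(datasets) {
      graphs <- lapply(datasets, function(d)
        detectCommunities(binarizeDensity(weightedGraph(
          regionTimeSeries(d, atlas), subjectId(d)), 0.5), 1))
      assembleFeatures(graphs,
        config = list(nodeMeasures = character(),
                      pairMeasures = "correlationWeight",
                      globalMeasures = character()))
    }
    ft1 <- featsOf(sim$datasets)
    ses2 <- lapply(sim$datasets, generateSessionPair, config = cfg,
                   truth = sim$truth)
    ft2 <- featsOf(ses2)
    y <- vapply(sim$datasets, groupLabel, character(1))
    mean(vapply(1:3, function(s)
      crossSessionEval(ft1, y, ft2, maxFeatures = 2, seed = s)$accuracy,
      numeric(1)))
  }
  accLow <- sessionAccuracy(0.02, 21)
  accHigh <- sessionAccuracy(0.6, 21)
  expect_gt(accLow, accHigh)
})
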