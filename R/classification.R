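#' Support vector machine specification
#'
#' Defaults follow the pipeline's reference configuration: a linear kernel
#' with box constraint C = 1. `rbfSigma` maps to the Gaussian kernel width
#' (gamma = 1 / (2 sigma^2)); `polyDegree` applies to the polynomial kernel
#' ("quadratic" is polynomial of degree 2).
#'
#' @param kernel one of `"linear"`, `"rbf"`, `"quadratic"`, `"polynomial"`.
#' @param boxConstraint positive C value, default 1.
#' @param rbfSigma RBF width, default 1.
#' @param polyDegree polynomial degree, default 3.
#' @return list used by the classification functions.
#' @export
classifierSpec <- function(kernel = c("linear", "rbf", "quadratic",
                                      "polynomial"),
                           boxConstraint = 1, rbfSigma = 1, polyDegree = 3L) {
  kernel <- match.arg(kernel)
  stopifnot(boxConstraint > 0)
  list(kernel = kernel, boxConstraint = boxConstraint,
       rbfSigma = rbfSigma, polyDegree = polyDegree)
}

svmArgs <- function(spec) {
  switch(spec$kernel,
    linear = list(kernel = "linear", cost = spec$boxConstraint),
    rbf = list(kernel = "radial", cost = spec$boxConstraint,
               gamma = 1 / (2 * spec$rbfSigma^2)),
    quadratic = list(kernel = "polynomial", cost = spec$boxConstraint,
                     degree = 2L, gamma = 1, coef0 = 1),
    polynomial = list(kernel = "polynomial", cost = spec$boxConstraint,
                      degree = spec$polyDegree, gamma = 1, coef0 = 1))
}

# Fit an SVM on pre-standardised data and return predictions for newx.
svmPredict <- function(x, y, newx, spec, weights = NULL) {
  x <- as.matrix(x); newx <- as.matrix(newx)
  args <- c(list(x = x, y = y, scale = FALSE), svmArgs(spec))
  fit <- do.call(e1071::svm, args)
  stats::predict(fit, newx)
}

standardiser <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  function(z) sweep(sweep(as.matrix(z), 2L, mu), 2L, sdv, "/")
}

# Mean validation accuracy of the feature subset `cols` across the rotation
# of inner folds. x is the standardised train+validation matrix.
innerCVAccuracy <- function(x, y, innerFold, cols, spec) {
  folds <- sort(unique(innerFold))
  acc <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    v <- innerFold == folds[fi]
    if (length(unique(y[!v])) < 2L)
      stop("degenerate inner split: one class absent from inner training set")
    pred <- svmPredict(x[!v, cols, drop = FALSE], y[!v],
                       x[v, cols, drop = FALSE], spec)
    acc[fi] <- mean(pred == y[v])
  }
  mean(acc)
}

#' Screen features by single-feature classification accuracy
#'
#' Each feature is used alone to train a classifier on the inner-training
#' folds and evaluated on the rotating validation fold; its score is the
#' mean validation accuracy over the inner rotation. Only features with
#' accuracy strictly above the threshold survive ("above 60%" by default).
#'
#' @param x standardised train+validation feature matrix (subjects x
#'   features, with column names).
#' @param y 2-level factor of labels.
#' @param innerFold integer inner-fold assignment per row of `x`.
#' @param spec a [classifierSpec()].
#' @param threshold screen threshold, default 0.60 (strict inequality).
#' @return list with `ids` (screened feature names, catalog order) and
#'   `accuracy` (named accuracies of all features).
#' @export
screenSingleFeatures <- function(x, y, innerFold, spec = classifierSpec(),
                                 threshold = 0.60) {
  acc <- vapply(seq_len(ncol(x)), function(j)
    innerCVAccuracy(x, y, innerFold, j, spec), numeric(1))
  names(acc) <- colnames(x)
  list(ids = colnames(x)[acc > threshold], accuracy = acc)
}

#' Sequential forward selection
#'
#' Greedy selection over the screened features: start from the feature with
#' the best single-feature inner-validation accuracy, then repeatedly add
#' the candidate that maximises the mean inner-validation accuracy of the
#' combined set, until `maxFeatures` features are selected (or candidates
#' are exhausted). Ties are broken by catalog (column) order. Step-1
#' accuracies are the screen accuracies, which use the identical folds.
#'
#' @param x standardised train+validation feature matrix.
#' @param y labels.
#' @param innerFold inner-fold assignment per row.
#' @param screened output of [screenSingleFeatures()].
#' @param spec a [classifierSpec()].
#' @param maxFeatures selection budget, default 40.
#' @return list with `sfsOrder` (feature ids in selection order) and
#'   `innerAccuracyByStep`.
#' @export
sfsSelect <- function(x, y, innerFold, screened, spec = classifierSpec(),
                      maxFeatures = 40L) {
  ids <- screened$ids
  if (!length(ids)) stop("no screened features to select from")
  acc <- screened$accuracy[ids]
  # earliest catalog position wins ties
  best <- ids[which.max(acc)]
  selected <- best
  stepAcc <- unname(acc[best])
  remaining <- setdiff(ids, best)
  while (length(selected) < min(maxFeatures, length(ids)) &&
         length(remaining)) {
    candAcc <- vapply(remaining, function(f)
      innerCVAccuracy(x, y, innerFold, c(selected, f), spec), numeric(1))
    pick <- remaining[which.max(candAcc)]
    stepAcc <- c(stepAcc, unname(max(candAcc)))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(sfsOrder = selected, innerAccuracyByStep = stepAcc)
}

#' Evaluate selected feature prefixes on a held-out test fold
#'
#' For each prefix length of the selection order, a classifier is trained on
#' all non-test subjects and applied to the test fold; accuracy
#' `(TP + TN)/T`, sensitivity `TP/P` and specificity `TN/N` are computed,
#' with patients as the positive class. If the test fold lacks a class the
#' corresponding rate is `NaN` while accuracy remains defined.
#'
#' @param xTrain,yTrain standardised non-test data and labels.
#' @param xTest,yTest standardised test data and labels.
#' @param sfsOrder feature ids in selection order.
#' @param spec a [classifierSpec()].
#' @return list with `testAccuracyByStep`, `predictionsByStep` (list), and
#'   `metricsAt(step)` helper data: per-step tp/tn/fp/fn matrix.
#' @export
evaluateFold <- function(xTrain, yTrain, xTest, yTest, sfsOrder,
                         spec = classifierSpec()) {
  nStep <- length(sfsOrder)
  accs <- numeric(nStep)
  preds <- vector("list", nStep)
  conf <- matrix(0L, nStep, 4L,
                 dimnames = list(NULL, c("tp", "tn", "fp", "fn")))
  pos <- levels(yTrain)[2]   # patient
  for (s in seq_len(nStep)) {
    cols <- sfsOrder[seq_len(s)]
    pred <- svmPredict(xTrain[, cols, drop = FALSE], yTrain,
                       xTest[, cols, drop = FALSE], spec)
    preds[[s]] <- pred
    accs[s] <- mean(pred == yTest)
    conf[s, ] <- c(sum(pred == pos & yTest == pos),
                   sum(pred != pos & yTest != pos),
                   sum(pred == pos & yTest != pos),
                   sum(pred != pos & yTest == pos))
  }
  list(testAccuracyByStep = accs, predictionsByStep = preds,
       confusionByStep = conf)
}

#' Run the full double cross-validation pipeline
#'
#' For every (partition, outer fold) unit: standardise features using
#' non-test statistics, screen single features on the inner rotation, run
#' sequential forward selection, then train on all non-test subjects and
#' evaluate every selection prefix on the held-out fold. The inner
#' (validation) accuracy curve is the single-CV performance; the test curve
#' is the double-CV performance. Per-subject misclassification counts use
#' each unit's best step: the prefix length maximising mean inner accuracy
#' (earliest on ties).
#'
#' @param ft a [FeatureTable-class] (or plain matrix with column names and
#'   row names as subject ids).
#' @param labels group labels, in `ft` subject order.
#' @param plan a [CVPlan-class] for the same subjects.
#' @param spec a [classifierSpec()].
#' @param screenThreshold single-feature screen threshold, default 0.60.
#' @param maxFeatures selection budget, default 40.
#' @param verbose print per-unit progress, default FALSE.
#' @return a [RunResults-class].
#' @export
runDoubleCV <- function(ft, labels, plan, spec = classifierSpec(),
                        screenThreshold = 0.60, maxFeatures = 40L,
                        verbose = FALSE) {
  X <- if (is(ft, "FeatureTable")) ft@matrix else as.matrix(ft)
  subjects <- if (is(ft, "FeatureTable")) ft@subjects else rownames(ft)
  stopifnot(identical(subjects, plan@subjects))
  y <- normaliseLabels(labels)
  stopifnot(identical(as.character(y), as.character(plan@labels)))
  pos <- levels(y)[2]
  miss <- integer(length(subjects))
  names(miss) <- subjects
  traces <- list()
  maxSteps <- maxFeatures
  singleMat <- NULL; doubleMat <- NULL
  pooled <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (p in seq_len(plan@nPartitions)) {
    f <- plan@outerFolds[[p]]
    for (fold in seq_len(plan@nOuterFolds)) {
      test <- f == fold
      std <- standardiser(X[!test, , drop = FALSE])
      xTr <- std(X[!test, , drop = FALSE])
      colnames(xTr) <- colnames(X)
      xTe <- std(X[test, , drop = FALSE])
      colnames(xTe) <- colnames(X)
      innerFold <- plan@innerFolds[[p]][[fold]]
      innerFold <- unname(innerFold[subjects[!test]])
      scr <- screenSingleFeatures(xTr, y[!test], innerFold, spec,
                                  screenThreshold)
      if (!length(scr$ids)) {
        # nothing survives the screen: fall back to the single best feature
        scr$ids <- names(which.max(scr$accuracy))
      }
      sel <- sfsSelect(xTr, y[!test], innerFold, scr, spec, maxFeatures)
      ev <- evaluateFold(xTr, y[!test], xTe, y[test], sel$sfsOrder, spec)
      bestStep <- which.max(sel$innerAccuracyByStep)
      predBest <- ev$predictionsByStep[[bestStep]]
      wrong <- predBest != y[test]
      miss[subjects[test]] <- miss[subjects[test]] + as.integer(wrong)
      pooled <- pooled + ev$confusionByStep[bestStep, ]
      traces[[length(traces) + 1L]] <- list(
        partition = p, fold = fold,
        screened = scr$ids, screenAccuracy = scr$accuracy,
        sfsOrder = sel$sfsOrder,
        innerAccuracyByStep = sel$innerAccuracyByStep,
        testAccuracyByStep = ev$testAccuracyByStep,
        bestStep = bestStep,
        testSubjects = subjects[test],
        predictions = predBest,
        confusion = ev$confusionByStep[bestStep, ])
      pad <- function(v) c(v, rep(NA_real_, maxSteps - length(v)))[seq_len(maxSteps)]
      singleMat <- rbind(singleMat, pad(sel$innerAccuracyByStep))
      doubleMat <- rbind(doubleMat, pad(ev$testAccuracyByStep))
      if (verbose)
        message(sprintf("partition %d fold %d: %d screened, best step %d, test acc %.3f",
                        p, fold, length(scr$ids), bestStep,
                        ev$testAccuracyByStep[bestStep]))
    }
  }
  curves <- data.frame(step = seq_len(maxSteps),
                       singleCV = colMeans(singleMat, na.rm = TRUE),
                       doubleCV = colMeans(doubleMat, na.rm = TRUE))
  P <- sum(pooled["tp"], pooled["fn"])
  N <- sum(pooled["tn"], pooled["fp"])
  summary <- list(
    accuracy = (pooled[["tp"]] + pooled[["tn"]]) / sum(pooled),
    sensitivity = if (P > 0) pooled[["tp"]] / P else NaN,
    specificity = if (N > 0) pooled[["tn"]] / N else NaN)
  names(y) <- subjects
  new("RunResults", traces = traces, misclassCounts = miss,
      nPartitions = plan@nPartitions, curves = curves, summary = summary,
      labels = y)
}

#' Per-subject misclassification rate
#'
#' `MR = M / nPartitions`: the proportion of a subject's test appearances in
#' which it was misclassified (at the fold's best feature count).
#'
#' @param results a [RunResults-class].
#' @return named numeric vector in `[0, 1]`.
#' @export
misclassificationRate <- function(results) {
  results@misclassCounts / results@nPartitions
}

#' Shuffled-label chance distribution
#'
#' Repeats the double cross-validation with randomly permuted labels,
#' returning the pooled accuracy of each repeat: the empirical distribution
#' of chance-level performance for this plan and feature table.
#'
#' @param ft feature table.
#' @param labels true labels (permuted internally).
#' @param plan a [CVPlan-class] template; each shuffle re-plans with a
#'   derived seed.
#' @param spec a [classifierSpec()].
#' @param nShuffles number of label permutations, default 10.
#' @param ... passed to [runDoubleCV()].
#' @return numeric vector of shuffled-label accuracies.
#' @export
shuffledChance <- function(ft, labels, plan, spec = classifierSpec(),
                           nShuffles = 10L, ...) {
  subjects <- if (is(ft, "FeatureTable")) ft@subjects else rownames(ft)
  y <- normaliseLabels(labels)
  out <- numeric(nShuffles)
  for (r in seq_len(nShuffles)) {
    ys <- withSeed(deriveSeed(plan@seed, 900000L + r), sample(y))
    planR <- makeCVPlan(subjects, ys, plan@nOuterFolds, plan@nInnerFolds,
                        plan@nPartitions, deriveSeed(plan@seed, 910000L + r))
    res <- runDoubleCV(ft, ys, planR, spec, ...)
    out[r] <- res@summary$accuracy
  }
  out
}
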