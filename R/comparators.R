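#' Independent feature selection
#'
#' Takes the top `k` screened features ranked by their single-feature
#' inner-validation accuracy (ties broken by catalog order) — the baseline
#' selector that ignores feature interactions.
#'
#' @param screened output of [screenSingleFeatures()].
#' @param k number of features, default 40.
#' @return character feature ids, best first.
#' @export
selectIndependent <- function(screened, k = 40L) {
  acc <- screened$accuracy[screened$ids]
  ord <- order(-acc, seq_along(acc))
  screened$ids[ord][seq_len(min(k, length(acc)))]
}

#' Feature ranking by Fisher's linear discriminant
#'
#' Computes the LDA direction `w = Sw^+ (mu1 - mu0)` with the Moore-Penrose
#' pseudo-inverse of the within-class scatter matrix `Sw` (always defined,
#' including when features outnumber subjects) and ranks features by the
#' absolute value of their weight.
#'
#' @param x feature matrix with column names.
#' @param y 2-level factor.
#' @param k number of features to return, default 40.
#' @return character feature ids, largest absolute weight first.
#' @export
selectLDA <- function(x, y, k = 40L) {
  y <- normaliseLabels(y)
  x <- as.matrix(x)
  g0 <- x[y == levels(y)[1], , drop = FALSE]
  g1 <- x[y == levels(y)[2], , drop = FALSE]
  if (nrow(g0) < 1L || nrow(g1) < 1L) stop("both classes must be present")
  Sw <- crossprod(sweep(g0, 2L, colMeans(g0))) +
        crossprod(sweep(g1, 2L, colMeans(g1)))
  w <- MASS::ginv(Sw) %*% (colMeans(g1) - colMeans(g0))
  ord <- order(-abs(w), seq_along(w))
  colnames(x)[ord][seq_len(min(k, ncol(x)))]
}

#' AdaBoost over linear SVM weak learners
#'
#' Discrete AdaBoost: `nWeak` weak classifiers are trained on weighted
#' resamples of the training set (sampling with replacement according to the
#' current sample weights), sample weights are re-normalised to sum to one
#' every round, and the prediction is the alpha-weighted vote. A round whose
#' weak learner degenerates (weighted error 0.5 or worse) is skipped with a
#' warning; a perfect weak learner ends the boosting early.
#'
#' @param xTrain,yTrain training data (standardised) and 2-level factor.
#' @param xTest data to predict.
#' @param spec a [classifierSpec()]; default linear, C = 1.
#' @param nWeak weak learners, default 10.
#' @param seed RNG seed for the weighted resampling.
#' @return list with `predictions` (factor for `xTest`), `alphas`, and
#'   `weightSums` (sample-weight totals per round, each 1 by construction).
#' @export
adaboostClassify <- function(xTrain, yTrain, xTest, spec = classifierSpec(),
                             nWeak = 10L, seed = 1L) {
  yTrain <- normaliseLabels(yTrain)
  n <- nrow(xTrain)
  wts <- rep(1 / n, n)
  ysign <- ifelse(yTrain == levels(yTrain)[2], 1, -1)
  score <- numeric(nrow(xTest))
  alphas <- numeric(0)
  weightSums <- numeric(0)
  withSeed(seed, {
    for (round in seq_len(nWeak)) {
      idx <- sample.int(n, n, replace = TRUE, prob = wts)
      if (length(unique(yTrain[idx])) < 2L) {
        warning("round ", round, " skipped: resample contains one class")
        next
      }
      predTrain <- svmPredict(xTrain[idx, , drop = FALSE], yTrain[idx],
                              xTrain, spec)
      h <- ifelse(predTrain == levels(yTrain)[2], 1, -1)
      err <- sum(wts[h != ysign])
      if (err >= 0.5) {
        warning("round ", round, " skipped: weak learner no better than chance")
        next
      }
      if (err == 0) {
        alpha <- 10   # cap: perfect learner dominates the vote
      } else {
        alpha <- 0.5 * log((1 - err) / err)
      }
      predTest <- svmPredict(xTrain[idx, , drop = FALSE], yTrain[idx],
                             xTest, spec)
      score <- score + alpha * ifelse(predTest == levels(yTrain)[2], 1, -1)
      alphas <- c(alphas, alpha)
      wts <- wts * exp(-alpha * ysign * h)
      wts <- wts / sum(wts)
      weightSums <- c(weightSums, sum(wts))
      if (err == 0) break
    }
  })
  pred <- factor(ifelse(score >= 0, levels(yTrain)[2], levels(yTrain)[1]),
                 levels = levels(yTrain))
  list(predictions = pred, alphas = alphas, weightSums = weightSums)
}

#' Train on session 1, classify session 2
#'
#' Performs the complete selection procedure (screen plus sequential forward
#' selection over an inner rotation) and final training on the session-1
#' data only, then applies the frozen feature set and model to the
#' session-2 features of the same subjects: a within-subject
#' generalisation test across scanning sessions.
#'
#' @param ft1 session-1 feature table ([FeatureTable-class] or matrix).
#' @param labels group labels for the shared subjects.
#' @param ft2 session-2 feature table, same subjects and feature columns.
#' @param spec a [classifierSpec()].
#' @param nInner inner folds for selection, default 4.
#' @param screenThreshold default 0.60.
#' @param maxFeatures default 40.
#' @param seed RNG seed for the inner fold draw.
#' @return list with `accuracy`, `predictions`, `sfsOrder`, `bestStep`.
#' @export
crossSessionEval <- function(ft1, labels, ft2, spec = classifierSpec(),
                             nInner = 4L, screenThreshold = 0.60,
                             maxFeatures = 40L, seed = 1L) {
  X1 <- if (is(ft1, "FeatureTable")) ft1@matrix else as.matrix(ft1)
  X2 <- if (is(ft2, "FeatureTable")) ft2@matrix else as.matrix(ft2)
  s1 <- if (is(ft1, "FeatureTable")) ft1@subjects else rownames(ft1)
  s2 <- if (is(ft2, "FeatureTable")) ft2@subjects else rownames(ft2)
  if (!identical(s1, s2)) stop("sessions must cover the same subjects")
  shared <- intersect(colnames(X1), colnames(X2))
  X1 <- X1[, shared, drop = FALSE]
  X2 <- X2[, shared, drop = FALSE]
  y <- normaliseLabels(labels)
  std <- standardiser(X1)
  x1 <- std(X1); colnames(x1) <- shared
  x2 <- std(X2); colnames(x2) <- shared
  innerFold <- withSeed(seed, foldAssignment(nrow(x1), nInner))
  scr <- screenSingleFeatures(x1, y, innerFold, spec, screenThreshold)
  if (!length(scr$ids)) scr$ids <- names(which.max(scr$accuracy))
  sel <- sfsSelect(x1, y, innerFold, scr, spec, maxFeatures)
  bestStep <- which.max(sel$innerAccuracyByStep)
  cols <- sel$sfsOrder[seq_len(bestStep)]
  pred <- svmPredict(x1[, cols, drop = FALSE], y, x2[, cols, drop = FALSE],
                     spec)
  list(accuracy = mean(pred == y), predictions = pred,
       sfsOrder = sel$sfsOrder, bestStep = bestStep)
}
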