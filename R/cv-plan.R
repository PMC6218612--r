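#' Build a nested cross-validation plan
#'
#' For each of `nPartitions` random partitions, subjects are split into
#' `nOuter` outer folds of equal size (remainders spread round-robin); each
#' fold serves once as the held-out test set, so every subject is tested
#' exactly `nPartitions` times. Within each outer training set the non-test
#' subjects are split into `nInner` inner folds that rotate as the
#' validation set during screening and sequential forward selection. If a
#' drawn outer fold lacks one of the classes the partition is re-drawn with
#' a warning, so degenerate folds are never silently accepted. Everything is
#' deterministic given `seed`.
#'
#' @param subjects character subject ids.
#' @param labels group labels (coercible to a 2-level factor; level order
#'   control, patient when those names are used).
#' @param nOuter outer folds, default 5.
#' @param nInner inner folds, default 4.
#' @param nPartitions random partitions, default 10.
#' @param seed RNG seed.
#' @return a [CVPlan-class].
#' @export
makeCVPlan <- function(subjects, labels, nOuter = 5L, nInner = 4L,
                       nPartitions = 10L, seed = 1L) {
  n <- length(subjects)
  if (n < nOuter) stop("fewer subjects (", n, ") than outer folds (", nOuter, ")")
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  labels <- normaliseLabels(labels)
  if (length(labels) != n) stop("one label per subject required")
  outer <- vector("list", nPartitions)
  inner <- vector("list", nPartitions)
  for (p in seq_len(nPartitions)) {
    f <- withSeed(deriveSeed(seed, p), {
      drawPartition(n, nOuter, labels)
    })
    outer[[p]] <- f
    inner[[p]] <- vector("list", nOuter)
    for (fold in seq_len(nOuter)) {
      trainIdx <- which(f != fold)
      assign4 <- withSeed(deriveSeed(seed, p * 1000L + fold), {
        drawInnerAssignment(length(trainIdx), nInner, labels[trainIdx])
      })
      names(assign4) <- subjects[trainIdx]
      inner[[p]][[fold]] <- assign4
    }
  }
  new("CVPlan", subjects = subjects, labels = labels,
      nOuterFolds = as.integer(nOuter), nInnerFolds = as.integer(nInner),
      nPartitions = as.integer(nPartitions), seed = as.integer(seed),
      outerFolds = outer, innerFolds = inner)
}

normaliseLabels <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (all(levels(labels) %in% c("control", "patient")))
    labels <- factor(labels, levels = c("control", "patient"))
  labels
}

foldAssignment <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sample(rep(seq_len(k), sizes))
}

# Inner rotation: every inner-training set (all folds but one) must retain
# both classes, otherwise no classifier can be fit; re-drawn quietly.
drawInnerAssignment <- function(n, nInner, labels, maxTries = 100L) {
  for (try in seq_len(maxTries)) {
    a <- foldAssignment(n, nInner)
    ok <- all(vapply(seq_len(nInner), function(v)
      length(unique(labels[a != v])) == 2L, logical(1)))
    if (ok) return(a)
  }
  stop("could not draw inner folds whose training sets keep both classes")
}

drawPartition <- function(n, nOuter, labels, maxTries = 100L) {
  for (try in seq_len(maxTries)) {
    f <- foldAssignment(n, nOuter)
    ok <- all(vapply(seq_len(nOuter), function(k)
      length(unique(labels[f == k])) == 2L, logical(1)))
    if (ok) {
      if (try > 1L)
        warning("re-drew partition ", try - 1L,
                " time(s) to avoid a single-class outer fold")
      return(f)
    }
  }
  stop("could not draw outer folds containing both classes")
}
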