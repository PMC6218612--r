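#' Effect size (d-prime) of a feature between groups
#'
#' `d' = (mean_patient - mean_control) / sqrt((var_patient + var_control)/2)`
#' (patient minus control), reported with the two-sided two-sample t-test
#' p-value.
#'
#' @param values numeric feature values.
#' @param labels 2-level factor (levels control, patient).
#' @return list with `dprime` and `pValue`.
#' @export
dPrime <- function(values, labels) {
  labels <- normaliseLabels(labels)
  a <- values[labels == levels(labels)[1]]   # control
  b <- values[labels == levels(labels)[2]]   # patient
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 subjects")
  pooled <- (stats::var(a) + stats::var(b)) / 2
  if (pooled == 0) stop("zero pooled variance")
  list(dprime = (mean(b) - mean(a)) / sqrt(pooled),
       pValue = stats::t.test(b, a)$p.value)
}

#' Correlate misclassification rate with symptom scores
#'
#' Pearson correlation with two-sided p-value between per-subject
#' misclassification rates and a clinical score.
#'
#' @param mr numeric misclassification rates.
#' @param scores numeric paired scores.
#' @return list with `r` and `pValue`.
#' @export
correlateScores <- function(mr, scores) {
  ok <- is.finite(mr) & is.finite(scores)
  mr <- mr[ok]; scores <- scores[ok]
  if (length(mr) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(mr) == 0 || stats::sd(scores) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(mr, scores, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value)
}
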