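#' Probability that one feature enters a random selection set
#'
#' The probability that a designated feature is included when `S` features
#' are drawn from `F` without replacement — the hypergeometric probability
#' of one success in `S` draws from a population of `F` with one marked
#' item, which reduces to `S / F`.
#'
#' @param F total number of candidate features.
#' @param S selection set size.
#' @return numeric probability in (0, 1].
#' @export
selectionProbability <- function(F, S) {
  if (S < 1 || S > F) stop("S must lie in [1, F]")
  S / F
}

#' Selection-frequency null parameters
#'
#' @param F number of candidate (screened) features.
#' @param S selection set size, default 40.
#' @param nFold number of independent selection sets, default 50.
#' @param alpha significance level, default 0.001.
#' @return list used by [frequencyPvalue()] and [significantFeatures()].
#' @export
frequencyNull <- function(F, S = 40L, nFold = 50L, alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  list(F = F, S = S, nFold = nFold,
       pSelect = selectionProbability(F, S), alpha = alpha)
}

#' Exact binomial tail p-value for a selection frequency
#'
#' Under the null each of the `nFold` selection sets includes a given
#' feature independently with probability `S / F`, so its total frequency is
#' Binomial(`nFold`, `S/F`). Returns `P(X >= n)` by exact summation of the
#' binomial mass.
#'
#' @param n observed selection frequency, `0 <= n <= nFold`.
#' @param null a [frequencyNull()].
#' @return numeric p-value.
#' @export
frequencyPvalue <- function(n, null) {
  stopifnot(n >= 0, n <= null$nFold)
  if (n == 0) return(1)
  sum(stats::dbinom(n:null$nFold, null$nFold, null$pSelect))
}

#' Expected null counts of the selection-frequency histogram
#'
#' `nFeatures * P(X = n)` for each frequency n: the expected number of
#' features appearing exactly n times if every set were drawn at random.
#'
#' @param nFeatures number of candidate features.
#' @param null a [frequencyNull()].
#' @return data.frame with `frequency` (0..nFold) and `expected`.
#' @export
expectedFrequencyCounts <- function(nFeatures, null) {
  n <- 0:null$nFold
  data.frame(frequency = n,
             expected = nFeatures * stats::dbinom(n, null$nFold, null$pSelect))
}

#' Features selected more often than chance
#'
#' Tallies how often each feature appears across the selection sets of a
#' completed run, computes the exact binomial tail p-value of each frequency
#' and flags features below `alpha`. The null's `F` defaults to the mean
#' screened-feature count over the run's folds (rounded), matching the use
#' of a single representative F.
#'
#' @param results a [RunResults-class].
#' @param alpha significance level, default 0.001.
#' @param F candidate-set size for the null; default mean screened count.
#' @param setSize selection set size for the null; default the run's
#'   maximum selection length.
#' @return data.frame (`featureId`, `frequency`, `pValue`, `significant`)
#'   sorted by descending frequency; the null parameters are attached as
#'   attribute `"null"`.
#' @export
significantFeatures <- function(results, alpha = 0.001, F = NULL,
                                setSize = NULL) {
  traces <- results@traces
  if (!length(traces)) stop("no selection traces in results")
  sets <- lapply(traces, `[[`, "sfsOrder")
  if (is.null(F))
    F <- round(mean(vapply(traces, function(tr) length(tr$screened),
                           numeric(1))))
  if (is.null(setSize)) setSize <- max(lengths(sets))
  setSize <- min(setSize, F)
  null <- frequencyNull(F, setSize, length(sets), alpha)
  tab <- table(unlist(sets))
  freq <- as.integer(tab)
  pv <- vapply(freq, frequencyPvalue, numeric(1), null = null)
  out <- data.frame(featureId = names(tab), frequency = freq,
                    pValue = pv, significant = pv < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$featureId), ]
  rownames(out) <- NULL
  attr(out, "null") <- null
  out
}

#' Smallest selection frequency flagged significant
#'
#' The least n with `P(X >= n) < alpha` under the binomial null — e.g. with
#' F = 1618 screened features, sets of 40 and 50 folds, frequencies of ten
#' or more are well beyond chance.
#'
#' @param null a [frequencyNull()].
#' @return integer frequency cutoff (NA if no frequency reaches alpha).
#' @export
frequencyCutoff <- function(null) {
  for (n in seq_len(null$nFold))
    if (frequencyPvalue(n, null) < null$alpha) return(n)
  NA_integer_
}
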