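featureCatalogFrame <- function(K, nodeMeasures, pairMeasures, globalMeasures) {
  ij <- pairIndexTable(K)
  rows <- list()
  for (m in nodeMeasures) {
    rows[[length(rows) + 1L]] <- data.frame(
      featureId = c(sprintf("%s_n%d", m, seq_len(K)),
                    paste0(m, "_mean"), paste0(m, "_sd")),
      measure = m,
      scope = c(rep("node", K), "mean", "sd"),
      nodeA = c(seq_len(K), NA, NA), nodeB = NA_integer_)
  }
  for (m in pairMeasures) {
    rows[[length(rows) + 1L]] <- data.frame(
      featureId = c(sprintf("%s_p%d_%d", m, ij[, 1], ij[, 2]),
                    paste0(m, "_mean"), paste0(m, "_sd")),
      measure = m,
      scope = c(rep("pair", nrow(ij)), "mean", "sd"),
      nodeA = c(ij[, 1], NA, NA), nodeB = c(ij[, 2], NA, NA))
  }
  for (m in globalMeasures) {
    rows[[length(rows) + 1L]] <- data.frame(
      featureId = m, measure = m, scope = "global",
      nodeA = NA_integer_, nodeB = NA_integer_)
  }
  do.call(rbind, rows)
}

#' Assemble a feature table from per-subject graphs
#'
#' Computes the measure registry for every subject graph and lays the values
#' out as one row per subject. Each node measure contributes K per-node
#' features plus its mean and standard deviation across nodes (K + 2
#' columns); each pair measure contributes K(K-1)/2 per-pair features plus
#' mean and sd (computed over finite values only); each global measure is a
#' single column. Any feature that is non-finite for at least one subject is
#' dropped for all subjects and recorded in the table's `dropped` slot, so
#' the retained matrix is entirely finite.
#'
#' @param graphs list of [SubjectGraph-class] objects sharing K, each with
#'   binary adjacency and communities.
#' @param subjects character subject ids (defaults to the graphs' ids).
#' @param config registry configuration passed to [measureRegistry()].
#' @return a [FeatureTable-class].
#' @examples
#' \donttest{
#' # a K = 90 atlas yields 92 columns per node measure and 4007 per pair
#' # measure before exclusion of non-finite features
#' }
#' @export
assembleFeatures <- function(graphs, subjects = NULL, config = list()) {
  stopifnot(length(graphs) >= 1L)
  K <- nrow(graphs[[1]]@weights)
  for (s in seq_along(graphs))
    if (nrow(graphs[[s]]@weights) != K)
      stop("subject ", s, " has a different number of regions (",
           nrow(graphs[[s]]@weights), " vs ", K, ")")
  if (is.null(subjects)) {
    subjects <- vapply(graphs, function(g) g@subjectId, character(1))
    if (any(subjects == "")) subjects <- sprintf("S%03d", seq_along(graphs))
  }
  reg1 <- measureRegistry(graphs[[1]], config)
  catalog <- featureCatalogFrame(K, names(reg1$node), names(reg1$pair),
                                 names(reg1$global))
  ij <- pairIndexTable(K)
  rowFor <- function(reg) {
    vals <- numeric(0)
    for (m in names(reg$node)) {
      v <- reg$node[[m]]
      fin <- v[is.finite(v)]
      vals <- c(vals, v, mean(fin), stats::sd(fin))
    }
    for (m in names(reg$pair)) {
      v <- reg$pair[[m]][ij]
      fin <- v[is.finite(v)]
      vals <- c(vals, v, mean(fin), stats::sd(fin))
    }
    c(vals, unname(reg$global))
  }
  mat <- matrix(NA_real_, length(graphs), nrow(catalog))
  mat[1, ] <- rowFor(reg1)
  for (s in seq_along(graphs)[-1])
    mat[s, ] <- rowFor(measureRegistry(graphs[[s]], config))
  colnames(mat) <- catalog$featureId
  bad <- !apply(is.finite(mat), 2L, all)
  dropped <- catalog$featureId[bad]
  mat <- mat[, !bad, drop = FALSE]
  catalog <- catalog[!bad, , drop = FALSE]
  rownames(catalog) <- NULL
  new("FeatureTable", matrix = mat, subjects = subjects,
      catalog = new("FeatureCatalog", entries = catalog),
      dropped = dropped)
}
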