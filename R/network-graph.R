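#' Average voxel series within atlas regions
#'
#' @param dataset a [VoxelDataset-class].
#' @param atlas a [VoxelAtlas-class] on the same voxel grid.
#' @return numeric matrix, time x regions; column r is the unweighted mean
#'   of the voxels labeled r.
#' @export
regionTimeSeries <- function(dataset, atlas) {
  if (!identical(dim(dataset@coords), dim(atlas@coords)) ||
      any(dataset@coords != atlas@coords))
    stop("dataset and atlas are not on the same voxel grid")
  K <- atlas@nRegions
  sizes <- tabulate(atlas@voxelRegionLabels, K)
  if (any(sizes == 0)) stop("empty region: ", which(sizes == 0)[1])
  out <- matrix(0, nrow(dataset@series), K)
  for (r in seq_len(K)) {
    cols <- atlas@voxelRegionLabels == r
    out[, r] <- rowMeans(dataset@series[, cols, drop = FALSE])
  }
  out
}

#' Build a subject's weighted region graph
#'
#' Pairwise Pearson correlation between region time series; negative
#' correlations are set to zero (their interpretation is contested and they
#' are rare in practice) and the diagonal is zeroed. The fraction of
#' negative off-diagonal correlations is recorded in the result.
#'
#' @param regionSeries time x region matrix from [regionTimeSeries()].
#' @param subjectId optional id stored on the graph.
#' @return a [SubjectGraph-class] with weights only.
#' @export
weightedGraph <- function(regionSeries, subjectId = "") {
  if (ncol(regionSeries) < 2L) stop("need at least 2 regions")
  sds <- apply(regionSeries, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region series at region ", which(sds == 0)[1])
  C <- stats::cor(regionSeries)
  dimnames(C) <- NULL
  diag(C) <- 0
  negFrac <- mean(C[upper.tri(C)] < 0)
  C[C < 0] <- 0
  C <- (C + t(C)) / 2
  new("SubjectGraph", weights = C, binary = matrix(numeric(0), 0, 0),
      densityTarget = NA_real_, communities = integer(),
      negativeFraction = negFrac, subjectId = subjectId)
}

#' Binarize a weighted graph at a target connection density
#'
#' Keeps exactly `floor(density * K(K-1)/2)` strongest weights as edges
#' (rank thresholding), which realises the stated density exactly even in
#' the presence of tied weights; ties at the cut are broken by
#' lexicographically smallest `(i, j)`.
#'
#' @param graph a [SubjectGraph-class].
#' @param density target connection density in (0, 1], default 0.30.
#' @return the graph with its `binary` slot filled.
#' @export
binarizeDensity <- function(graph, density = 0.30) {
  stopifnot(is(graph, "SubjectGraph"), density > 0, density <= 1)
  K <- nrow(graph@weights)
  ij <- pairIndexTable(K)
  w <- graph@weights[ij]
  m <- floor(density * K * (K - 1) / 2)
  ord <- order(-w, ij[, 1], ij[, 2])
  B <- matrix(0, K, K)
  keep <- ij[ord[seq_len(m)], , drop = FALSE]
  B[keep] <- 1
  B[keep[, 2:1, drop = FALSE]] <- 1
  initialize(graph, binary = B, densityTarget = density)
}

#' Louvain community detection on the weighted graph
#'
#' Runs Louvain modularity optimisation on the weighted (not binarized)
#' graph; the partition is deterministic given `seed`. Used by
#' module-aware node measures (participation coefficient, within-module
#' degree) and the modularity global measure.
#'
#' @param graph a [SubjectGraph-class].
#' @param seed RNG seed, default 1.
#' @return the graph with its `communities` slot filled.
#' @export
detectCommunities <- function(graph, seed = 1L) {
  stopifnot(is(graph, "SubjectGraph"))
  g <- igraph::graph_from_adjacency_matrix(graph@weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- withSeed(seed, igraph::membership(igraph::cluster_louvain(g)))
  initialize(graph, communities = as.integer(memb))
}

#' Modularity of a partition of a subject graph
#'
#' @param graph a [SubjectGraph-class].
#' @param membership integer partition; defaults to the stored communities.
#' @param use `"weights"` (default) or `"binary"`.
#' @return Newman modularity Q.
#' @export
graphModularity <- function(graph, membership = communities(graph),
                            use = c("weights", "binary")) {
  use <- match.arg(use)
  W <- if (use == "weights") graph@weights else graph@binary
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

binaryIgraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph@binary, mode = "undirected",
                                      diag = FALSE)
}
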