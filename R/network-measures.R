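#' Shortest-path distance between all node pairs of the binary graph
#'
#' Unweighted (hop-count) shortest paths; unreachable pairs are `Inf` and
#' propagate as non-finite values into feature assembly, where the stated
#' exclusion rule drops them.
#'
#' @param graph a [SubjectGraph-class] with its binary slot filled.
#' @return K x K symmetric matrix, zero diagonal.
#' @export
pairDistance <- function(graph) {
  requireBinary(graph)
  D <- igraph::distances(binaryIgraph(graph), algorithm = "unweighted")
  dimnames(D) <- NULL
  D
}

#' Matching index between all node pairs
#'
#' Similarity of two nodes' connectivity profiles from their common
#' neighbors. The default `"jaccard"` convention divides the number of
#' common neighbors (excluding the pair itself) by the size of the union of
#' the two neighbor sets (excluding the pair); the `"bct"` convention
#' divides twice the common-neighbor count by the summed degrees excluding
#' any i-j edge. Both are 1 for identical profiles and 0 for disjoint ones;
#' pairs whose neighbor union is empty get 0.
#'
#' @param graph a [SubjectGraph-class] with its binary slot filled.
#' @param variant `"jaccard"` (default) or `"bct"`.
#' @return K x K symmetric matrix in `[0, 1]`, zero diagonal.
#' @export
pairMatchingIndex <- function(graph, variant = c("jaccard", "bct")) {
  variant <- match.arg(variant)
  requireBinary(graph)
  B <- graph@binary
  deg <- rowSums(B)
  common <- B %*% B              # [i,j] = common neighbors of i and j (k != i,j)
  degExcl <- outer(deg, deg, "+") - 2 * B   # |N(i)\{j}| + |N(j)\{i}|
  denom <- if (variant == "jaccard") degExcl - common else degExcl
  num <- if (variant == "jaccard") common else 2 * common
  M <- ifelse(denom > 0, num / denom, 0)
  diag(M) <- 0
  dimnames(M) <- NULL
  (M + t(M)) / 2
}

# m-step reachability sets: R[i, k] = 1 iff k != i reachable from i in <= m
reachabilitySets <- function(B, m) {
  K <- nrow(B)
  P <- diag(K) + B
  Rm <- P
  if (m > 1L) for (s in seq_len(m - 1L)) Rm <- Rm %*% P
  Rm <- (Rm > 0) * 1
  diag(Rm) <- 0
  Rm
}

#' Generalized topological overlap between all node pairs
#'
#' GTOM-m measures the extent to which two nodes share the same m-step
#' neighborhoods: with `N_m(i)` the set of nodes reachable from i within m
#' steps (excluding i itself),
#' `gtom(i,j) = (|N_m(i) inter N_m(j)| + a_ij) / (min(|N_m(i)|, |N_m(j)|) + 1 - a_ij)`.
#'
#' @param graph a [SubjectGraph-class] with its binary slot filled.
#' @param m neighborhood depth, default 2.
#' @return K x K symmetric matrix, zero diagonal.
#' @export
pairGtom <- function(graph, m = 2L) {
  requireBinary(graph)
  stopifnot(m >= 1L)
  B <- graph@binary
  Rm <- reachabilitySets(B, m)
  inter <- Rm %*% t(Rm)          # [i,j] = |N_m(i) inter N_m(j)|
  sizes <- rowSums(Rm)
  minSize <- outer(sizes, sizes, pmin)
  G <- (inter + B) / (minSize + 1 - B)
  diag(G) <- 0
  dimnames(G) <- NULL
  (G + t(G)) / 2
}

#' Edge betweenness between all node pairs
#'
#' Betweenness of the binary edge i-j; non-adjacent pairs get 0.
#' @param graph a [SubjectGraph-class] with its binary slot filled.
#' @return K x K symmetric matrix.
#' @export
pairEdgeBetweenness <- function(graph) {
  requireBinary(graph)
  g <- binaryIgraph(graph)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  K <- nrow(graph@binary)
  M <- matrix(0, K, K)
  M[el] <- eb
  M[el[, 2:1, drop = FALSE]] <- eb
  M
}

#' Raw common-neighbor count between all node pairs
#'
#' `|N(i) inter N(j)|` excluding the pair itself (unnormalised neighborhood
#' overlap).
#' @param graph a [SubjectGraph-class] with its binary slot filled.
#' @return K x K symmetric matrix of counts.
#' @export
pairNeighborhoodOverlap <- function(graph) {
  requireBinary(graph)
  M <- graph@binary %*% graph@binary
  diag(M) <- 0
  dimnames(M) <- NULL
  M
}

requireBinary <- function(graph) {
  if (!length(graph@binary))
    stop("graph has no binary adjacency; call binarizeDensity() first")
  invisible(TRUE)
}

requireCommunities <- function(graph) {
  if (!length(graph@communities))
    stop("graph has no community partition; call detectCommunities() first")
  invisible(TRUE)
}

# --- node measures -----------------------------------------------------

nodeClustering <- function(graph) {
  cc <- igraph::transitivity(binaryIgraph(graph), type = "localundirected",
                             isolates = "zero")
  cc
}

nodeLocalEfficiency <- function(graph) {
  B <- graph@binary
  K <- nrow(B)
  out <- numeric(K)
  for (i in seq_len(K)) {
    nb <- which(B[i, ] > 0)
    if (length(nb) < 2L) { out[i] <- 0; next }
    sub <- B[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    d <- igraph::distances(g, algorithm = "unweighted")
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    out[i] <- mean(inv)
  }
  out
}

nodeParticipation <- function(graph) {
  requireCommunities(graph)
  B <- graph@binary
  deg <- rowSums(B)
  memb <- graph@communities
  K <- nrow(B)
  p <- numeric(K)
  for (i in seq_len(K)) {
    if (deg[i] == 0) { p[i] <- 0; next }
    ks <- tapply(B[i, ], memb, sum)
    p[i] <- 1 - sum((ks / deg[i])^2)
  }
  p
}

nodeWithinModuleZ <- function(graph) {
  requireCommunities(graph)
  B <- graph@binary
  memb <- graph@communities
  K <- nrow(B)
  z <- numeric(K)
  for (mod in unique(memb)) {
    nodes <- which(memb == mod)
    kin <- rowSums(B[nodes, nodes, drop = FALSE])
    s <- stats::sd(kin)
    z[nodes] <- if (is.na(s) || s == 0) 0 else (kin - mean(kin)) / s
  }
  z
}

nodeCloseness <- function(graph) {
  D <- pairDistance(graph)
  K <- nrow(D)
  vapply(seq_len(K), function(i) {
    d <- D[i, -i]
    if (all(is.finite(d))) (K - 1) / sum(d) else NA_real_
  }, numeric(1))
}

# --- global measures ---------------------------------------------------

globalFromDistance <- function(D) {
  up <- D[upper.tri(D)]
  finite <- is.finite(up)
  inv <- ifelse(finite, 1 / up, 0)
  inv[up == 0] <- 0
  list(
    characteristicPathLength = if (any(finite)) mean(up[finite]) else NA_real_,
    globalEfficiency = mean(inv)
  )
}

#' Compute the registry of graph-theoretic measures for one subject graph
#'
#' Node measures (one value per node): degree, strength (weighted degree),
#' clustering coefficient, local efficiency, betweenness centrality,
#' eigenvector centrality, closeness, k-coreness, participation coefficient
#' and within-module degree z-score (the latter two need communities). Pair
#' measures (one value per unordered node pair): shortest-path distance,
#' matching index, generalized topological overlap, edge betweenness, raw
#' neighborhood overlap and the correlation weight itself. Global measures:
#' characteristic path length, global efficiency, transitivity, degree
#' assortativity, modularity of the detected partition, realised density,
#' mean clustering, largest-component fraction, diameter and radius.
#'
#' Values that are undefined for a particular graph (e.g. distances between
#' unreachable nodes, assortativity of a regular graph) are returned
#' non-finite and excluded later by [assembleFeatures()].
#'
#' @param graph a [SubjectGraph-class] with binary adjacency and
#'   communities.
#' @param config list of registry options: `gtomSteps` (default 2),
#'   `matchingVariant` (`"jaccard"` or `"bct"`), and character vectors
#'   `nodeMeasures`, `pairMeasures`, `globalMeasures` to subset the
#'   registry.
#' @return list with elements `node` (named list of length-K vectors),
#'   `pair` (named list of K x K matrices) and `global` (named numerics).
#' @export
measureRegistry <- function(graph, config = list()) {
  requireBinary(graph)
  requireCommunities(graph)
  gtomSteps <- config$gtomSteps %||% 2L
  variant <- config$matchingVariant %||% "jaccard"
  B <- graph@binary
  K <- nrow(B)
  g <- binaryIgraph(graph)
  D <- pairDistance(graph)

  node <- list(
    degree = rowSums(B),
    strength = rowSums(graph@weights),
    clustering = nodeClustering(graph),
    localEfficiency = nodeLocalEfficiency(graph),
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    eigenvector = as.numeric(igraph::eigen_centrality(g)$vector),
    closeness = nodeCloseness(graph),
    coreness = as.numeric(igraph::coreness(g)),
    participation = nodeParticipation(graph),
    withinModuleZ = nodeWithinModuleZ(graph)
  )
  pair <- list(
    distance = D,
    matchingIndex = pairMatchingIndex(graph, variant),
    gtom = pairGtom(graph, gtomSteps),
    edgeBetweenness = pairEdgeBetweenness(graph),
    neighborhoodOverlap = pairNeighborhoodOverlap(graph),
    correlationWeight = graph@weights
  )
  comps <- igraph::components(g)
  gl <- globalFromDistance(D)
  globalM <- c(
    characteristicPathLength = gl$characteristicPathLength,
    globalEfficiency = gl$globalEfficiency,
    transitivity = igraph::transitivity(g, type = "global"),
    assortativity = suppressWarnings(igraph::assortativity_degree(g)),
    modularity = graphModularity(graph),
    density = sum(B[upper.tri(B)]) / (K * (K - 1) / 2),
    meanClustering = mean(node$clustering),
    largestComponentFraction = max(comps$csize) / K,
    diameter = suppressWarnings(max(D[upper.tri(D)][is.finite(D[upper.tri(D)])])),
    radius = {
      ecc <- apply(D, 1L, function(r) max(r[is.finite(r)]))
      min(ecc)
    }
  )
  if (!is.null(config$nodeMeasures)) node <- node[config$nodeMeasures]
  if (!is.null(config$pairMeasures)) pair <- pair[config$pairMeasures]
  if (!is.null(config$globalMeasures))
    globalM <- globalM[config$globalMeasures]
  list(node = node, pair = pair, global = globalM)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
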