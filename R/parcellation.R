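#' Concatenate datasets over time
#'
#' Stacks the time series of several subject-sessions voxel by voxel, in
#' input order, producing a single long series per voxel for group-level
#' atlas construction. All datasets must share identical voxel coordinates.
#'
#' @param datasets list of [VoxelDataset-class] objects.
#' @return a [VoxelDataset-class] with `sum(T)` rows, subject id `"group"`.
#' @export
concatenateGroup <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset")
  ref <- datasets[[1]]@coords
  for (d in seq_along(datasets)) {
    cc <- datasets[[d]]@coords
    if (!identical(dim(cc), dim(ref)) || any(cc != ref)) {
      bad <- if (identical(dim(cc), dim(ref)))
        which(rowSums(cc != ref) > 0)[1] else 1L
      stop("dataset ", d, " coordinates differ from dataset 1 at voxel ", bad)
    }
  }
  series <- do.call(rbind, lapply(datasets, function(d) d@series))
  new("VoxelDataset", subjectId = "group", sessionId = "concat",
      groupLabel = datasets[[1]]@groupLabel, coords = ref, series = series)
}

#' Pearson correlation matrix between columns
#'
#' Computes the correlation adjacency matrix of a time-by-voxel matrix:
#' columns are mean-centred, cross-products are normalised by the column
#' norms, entries are clipped to `[-1, 1]` against rounding and the diagonal
#' is set exactly to 1. On prewhitened (mean-free) input the centring is a
#' no-op and the result equals plain cosine similarity of the series.
#'
#' @param series numeric matrix, time x voxels, at least 2 rows.
#' @param maxVoxels guardrail on the number of columns before the dense
#'   N x N matrix is materialised, default 5000.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
correlationMatrix <- function(series, maxVoxels = 5000L) {
  if (nrow(series) < 2L) stop("need at least 2 time points")
  if (ncol(series) > maxVoxels)
    stop("refusing to materialise a ", ncol(series), "^2 correlation matrix; ",
         "downsample the grid or raise maxVoxels")
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column at voxel ", which(sds == 0)[1])
  C <- stats::cor(series)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  (C + t(C)) / 2
}

#' Correlation distance
#'
#' `D = 1 - C`: 0 for perfectly correlated pairs, 1 for uncorrelated pairs
#' and 2 for perfectly anticorrelated pairs.
#'
#' @param C a correlation matrix (as from [correlationMatrix()]).
#' @return distance matrix with zero diagonal, entries in `[0, 2]`.
#' @export
correlationDistance <- function(C) {
  D <- 1 - C
  diag(D) <- 0
  D[D < 0] <- 0
  D[D > 2] <- 2
  D
}

#' Spatially constrained agglomerative Ward clustering
#'
#' Agglomerates voxels under Ward's minimum-variance criterion while only
#' allowing merges of clusters that contain at least one pair of spatially
#' neighboring voxels, so every cluster at every level is contiguous.
#'
#' The supplied distances are squared internally and merged with the
#' Lance-Williams update for Ward's method; recorded merge heights are the
#' square roots of the Ward criterion, matching the convention of
#' `hclust(method = "ward.D2")`, which this function reproduces exactly when
#' the adjacency is fully connected. Ties in the criterion are broken by the
#' lexicographically smallest `(clusterA, clusterB)` id pair, making the
#' merge sequence deterministic.
#'
#' @param D symmetric distance matrix (e.g. [correlationDistance()]).
#' @param coords integer voxel coordinates, one row per leaf of `D`.
#' @param connectivity spatial neighborhood rule: 6 (faces, default), 18 or
#'   26; or the string `"full"` for unconstrained clustering.
#' @return a [WardDendrogram-class].
#' @export
constrainedWard <- function(D, coords, connectivity = 6L) {
  n <- nrow(D)
  stopifnot(ncol(D) == n, nrow(coords) == n)
  if (n < 2L) stop("need at least 2 voxels")
  full <- identical(connectivity, "full")
  if (full) {
    A <- matrix(TRUE, n, n)
    diag(A) <- FALSE
  } else {
    if (!voxelGraphConnected(coords, connectivity))
      stop("voxel adjacency graph is disconnected; ",
           "a full merge tree is impossible")
    A <- matrix(FALSE, n, n)
    pr <- adjacencyPairs(coords, connectivity)
    A[pr] <- TRUE
    A[pr[, 2:1, drop = FALSE]] <- TRUE
  }
  W <- D^2                      # Ward criterion tracked on squared distances
  active <- rep(TRUE, n)
  sizes <- rep(1, n)
  ids <- seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  BIG <- Inf
  for (step in seq_len(n - 1L)) {
    M <- W
    M[!A] <- BIG
    M[lower.tri(M, diag = TRUE)] <- BIG
    M[!active, ] <- BIG
    M[, !active] <- BIG
    best <- min(M)
    if (!is.finite(best))
      stop("no spatially admissible merge remains at step ", step)
    cand <- which(M == best, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # ties: smallest (idA, idB) pair, ids sorted within the pair
      ca <- pmin(ids[cand[, 1]], ids[cand[, 2]])
      cb <- pmax(ids[cand[, 1]], ids[cand[, 2]])
      cand <- cand[order(ca, cb)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    idA <- min(ids[i], ids[j]); idB <- max(ids[i], ids[j])
    merges[step, ] <- c(idA, idB)
    heights[step] <- sqrt(max(best, 0))
    # Lance-Williams Ward update of the squared criterion for merged cluster
    k <- which(active); k <- k[k != i & k != j]
    if (length(k)) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      newW <- ((ni + nk) * W[i, k] + (nj + nk) * W[j, k] - nk * best) /
        (ni + nj + nk)
      W[i, k] <- newW
      W[k, i] <- newW
    }
    A[i, ] <- A[i, ] | A[j, ]
    A[, i] <- A[, i] | A[, j]
    A[i, i] <- FALSE
    active[j] <- FALSE
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- n + step
  }
  cc <- coords
  storage.mode(cc) <- "integer"
  new("WardDendrogram", merges = merges, heights = heights,
      nLeaves = as.integer(n), coords = cc)
}

#' Cut a dendrogram into K regions
#'
#' Replays the first `nLeaves - K` merges of the dendrogram and labels the
#' resulting clusters 1..K in order of their smallest member voxel index.
#' Cuts of a spatially constrained dendrogram are contiguous by
#' construction.
#'
#' @param dendro a [WardDendrogram-class].
#' @param K desired number of regions, `1 <= K <= nLeaves`.
#' @return a [VoxelAtlas-class].
#' @export
cutDendrogram <- function(dendro, K) {
  n <- dendro@nLeaves
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must lie in [1, ", n, "]")
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (step in seq_len(n - K)) {
    a <- find(dendro@merges[step, 1])
    b <- find(dendro@merges[step, 2])
    newId <- n + step
    parent[a] <- newId
    parent[b] <- newId
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- as.integer(factor(roots, levels = unique(roots[order(seq_len(n))])))
  # unique() keeps first-appearance order, i.e. smallest member voxel index
  new("VoxelAtlas", voxelRegionLabels = labels, nRegions = K,
      coords = dendro@coords)
}

#' Overlap of atlas regions with a reference labeling
#'
#' For each atlas region, the percentage of its voxels covered by each
#' reference label, sorted by descending overlap. Mirrors the convention of
#' describing data-driven regions by the anatomical labels they overlap.
#'
#' @param atlas,reference [VoxelAtlas-class] objects on the same voxel set.
#' @return data.frame with columns `region`, `referenceLabel`,
#'   `percentOverlap`.
#' @export
atlasOverlapReport <- function(atlas, reference) {
  if (!identical(dim(atlas@coords), dim(reference@coords)) ||
      any(atlas@coords != reference@coords))
    stop("atlas and reference are not on the same voxel grid")
  out <- list()
  for (r in seq_len(atlas@nRegions)) {
    inR <- atlas@voxelRegionLabels == r
    tab <- table(reference@voxelRegionLabels[inR])
    pct <- 100 * as.numeric(tab) / sum(inR)
    ord <- order(-pct)
    out[[r]] <- data.frame(region = r,
                           referenceLabel = as.integer(names(tab))[ord],
                           percentOverlap = pct[ord])
  }
  do.call(rbind, out)
}
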