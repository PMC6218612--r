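# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

# Linear index <-> 3D grid coordinate bookkeeping (1-based).
gridCoords <- function(dims) {
  m <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3]), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

# Neighbor offsets for 6/18/26-connectivity on a 3D grid.
connectivityOffsets <- function(connectivity = 6L) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  norm1 <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6"  = norm1 == 1,
    "18" = norm1 >= 1 & rowSums(off != 0) <= 2,
    "26" = norm1 >= 1,
    stop("connectivity must be one of 6, 18, 26")
  )
  off[keep, , drop = FALSE]
}

#' Spatial adjacency between voxels
#'
#' Builds the sparse neighbor structure of a set of integer 3D voxel
#' coordinates under face (6), edge (18) or corner (26) connectivity.
#'
#' @param coords integer matrix, voxels x 3.
#' @param connectivity 6, 18 or 26.
#' @return list of integer vectors: the neighbors of each voxel (indices
#'   into `coords` rows).
#' @export
voxelAdjacency <- function(coords, connectivity = 6L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  pr <- adjacencyPairs(coords, connectivity)
  nbrs <- rep(list(integer()), nrow(coords))
  if (nrow(pr)) {
    both <- rbind(pr, pr[, 2:1, drop = FALSE])
    sp <- split(both[, 2], both[, 1])
    for (nm in names(sp)) nbrs[[as.integer(nm)]] <- sort(unname(sp[[nm]]))
  }
  nbrs
}

# Faster vectorised adjacency: returns a 2-column matrix of index pairs
# (i < j) that are spatial neighbors.
adjacencyPairs <- function(coords, connectivity = 6L) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  idx <- seq_len(nrow(coords))
  lookup <- structure(idx, names = key(coords))
  off <- connectivityOffsets(connectivity)
  pairs <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    shifted <- sweep(coords, 2L, off[o, ], "+")
    hit <- unname(lookup[key(shifted)])
    ok <- !is.na(hit)
    pairs[[o]] <- cbind(idx[ok], hit[ok])
  }
  pr <- do.call(rbind, pairs)
  pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
  unique(pr)
}

# Is the voxel graph connected?
voxelGraphConnected <- function(coords, connectivity = 6L) {
  n <- nrow(coords)
  if (n <= 1L) return(TRUE)
  pr <- adjacencyPairs(coords, connectivity)
  g <- igraph::graph_from_edgelist(pr, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::is_connected(g)
}

# Upper-triangle index helpers (column-major over i < j).
pairIndexTable <- function(K) {
  ij <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

# Nearest correlation matrix by eigenvalue clipping and renormalisation.
projectToCorrelation <- function(C, minEigen = 1e-8) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, minEigen)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 <- C2 / tcrossprod(d)
  diag(C2) <- 1
  (C2 + t(C2)) / 2
}
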