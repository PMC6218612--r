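# Independent oracles used across the suite: deliberately naive
# implementations (direct sums, explicit set operations, exhaustive
# enumeration) kept separate from the package's computational paths.

# Direct O(T^2) discrete Fourier transform.
dftOracle <- function(x) {
  Tn <- length(x)
  k <- 0:(Tn - 1)
  vapply(k, function(f)
    sum(x * exp(-2i * pi * f * k / Tn)), complex(1))
}

idftOracle <- function(X) {
  Tn <- length(X)
  k <- 0:(Tn - 1)
  vapply(k, function(t)
    sum(X * exp(2i * pi * k * t / Tn)) / Tn, complex(1))
}

# Spectral flattening computed entirely through the direct DFT.
prewhitenOracle <- function(x, zeroTol = 1e-12) {
  X <- dftOracle(x)
  mag <- Mod(X)
  keep <- mag > zeroTol * max(mag)
  keep[1] <- FALSE
  Y <- complex(length(x))
  Y[keep] <- X[keep] / mag[keep]
  Re(idftOracle(Y))
}

# Scalar Pearson formula applied to one pair of vectors.
pearsonOracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Hop-count shortest paths by breadth-first expansion of matrix powers.
bfsDistanceOracle <- function(B) {
  K <- nrow(B)
  D <- matrix(Inf, K, K)
  diag(D) <- 0
  reach <- diag(K)
  P <- diag(K)
  for (step in seq_len(K)) {
    P <- (P %*% (diag(K) + B) > 0) * 1
    new <- P > 0 & reach == 0
    D[new] <- step
    reach[new] <- 1
    if (all(reach > 0)) break
  }
  D
}

# Matching index by explicit neighbor-set operations.
matchingOracle <- function(B, variant = "jaccard") {
  K <- nrow(B)
  M <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    Ni <- setdiff(which(B[i, ] > 0), c(i, j))
    Nj <- setdiff(which(B[j, ] > 0), c(i, j))
    common <- length(intersect(Ni, Nj))
    denom <- if (variant == "jaccard") length(union(Ni, Nj))
             else length(Ni) + length(Nj)
    num <- if (variant == "jaccard") common else 2 * common
    M[i, j] <- if (denom > 0) num / denom else 0
  }
  M
}

# m-step reachability set of node i, excluding i (explicit BFS).
reachSetOracle <- function(B, i, m) {
  frontier <- i
  seen <- i
  for (s in seq_len(m)) {
    frontier <- setdiff(which(colSums(B[frontier, , drop = FALSE]) > 0), seen)
    if (!length(frontier)) break
    seen <- union(seen, frontier)
  }
  setdiff(seen, i)
}

gtomOracle <- function(B, m) {
  K <- nrow(B)
  G <- matrix(0, K, K)
  sets <- lapply(seq_len(K), reachSetOracle, B = B, m = m)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    a <- B[i, j]
    G[i, j] <- (length(intersect(sets[[i]], sets[[j]])) + a) /
      (min(length(sets[[i]]), length(sets[[j]])) + 1 - a)
  }
  G
}

# Local clustering coefficient by direct triangle counting.
clusteringOracle <- function(B) {
  K <- nrow(B)
  vapply(seq_len(K), function(i) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(B[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

# Node betweenness from first principles: count shortest paths with the
# path-count recursion over BFS layers, then sum pair dependencies.
betweennessOracle <- function(B) {
  K <- nrow(B)
  D <- bfsDistanceOracle(B)
  # sigma[s, t]: number of shortest s-t paths
  sigma <- matrix(0, K, K)
  for (s in seq_len(K)) {
    sig <- numeric(K)
    sig[s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(B[, v] > 0 & D[s, ] == D[s, v] - 1)
      sig[v] <- sum(sig[pred])
    }
    sigma[s, ] <- sig
  }
  bc <- numeric(K)
  for (v in seq_len(K)) {
    tot <- 0
    for (s in seq_len(K)) for (t in seq_len(K)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- tot / 2   # each unordered pair counted twice
  }
  bc
}

# Newman modularity of a partition, from the definition.
modularityOracle <- function(W, memb) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (memb[i] == memb[j]) q <- q + W[i, j] - k[i] * k[j] / m2
  q / m2
}

# Symmetric binary adjacency from an edge-presence bit vector (upper
# triangle, row-major over i < j).
graphFromBits <- function(n, bits) {
  B <- matrix(0, n, n)
  B[t(utils::combn(n, 2))] <- bits
  B + t(B)
}

allGraphs <- function(n) {
  nb <- n * (n - 1) / 2
  lapply(0:(2^nb - 1), function(code)
    graphFromBits(n, as.integer(intToBits(code))[seq_len(nb)]))
}

randomBinaryGraph <- function(n, p = 0.4) {
  nb <- n * (n - 1) / 2
  graphFromBits(n, stats::rbinom(nb, 1, p))
}

# Wrap a plain binary adjacency as a SubjectGraph (weights = binary).
graphFromBinary <- function(B) {
  new("SubjectGraph", weights = B * 1, binary = B * 1,
      densityTarget = NA_real_, communities = integer(),
      negativeFraction = 0, subjectId = "toy")
}

# Total within-cluster sum of squares of 1D values under a labeling.
wardObjectiveOracle <- function(values, labels) {
  sum(vapply(unique(labels), function(l) {
    v <- values[labels == l]
    sum((v - mean(v))^2)
  }, numeric(1)))
}

# Agreement of two labelings up to renaming.
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Quick synthetic feature table: n subjects, p noise features, plus
# optional informative columns separated by `effect` between groups.
randomFeatureTable <- function(n, p, effect = 0, nInformative = 0,
                               seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  y <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%03d", seq_len(p))
  if (nInformative > 0)
    X[y == "patient", seq_len(nInformative)] <-
      X[y == "patient", seq_len(nInformative)] + effect
  rownames(X) <- sprintf("S%03d", seq_len(n))
  list(X = X, y = y, subjects = rownames(X))
}
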