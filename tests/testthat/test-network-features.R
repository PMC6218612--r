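test_that("region time series are unweighted voxel means", {
  coords <- cbind(1:4, 1L, 1L)
  atlas <- new("VoxelAtlas", voxelRegionLabels = c(1L, 1L, 2L, 2L),
               nRegions = 2L, coords = coords)
  s <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8), nrow = 2, byrow = TRUE)
  d <- new("VoxelDataset", subjectId = "S", sessionId = "s", groupLabel = "control",
           coords = coords, series = s)
  rt <- regionTimeSeries(d, atlas)
  expect_equal(rt[, 1], c(1.5, 5.5))
  expect_equal(rt[, 2], c(3.5, 7.5))

  singles <- new("VoxelAtlas", voxelRegionLabels = c(2L, 1L, 4L, 3L),
                 nRegions = 4L, coords = coords)
  expect_equal(regionTimeSeries(d, singles), s[, c(2, 1, 4, 3)])
})

test_that("weighted graphs zero negative correlations and track their fraction", {
  set.seed(1)
  t <- rnorm(100)
  series <- cbind(t, -t + rnorm(100, sd = 0.1), rnorm(100), t + rnorm(100, sd = 0.4))
  g <- weightedGraph(series)
  W <- weightsMatrix(g)
  expect_equal(W[1, 2], 0)                      # anticorrelated pair zeroed
  expect_gt(W[1, 4], 0.8)                       # correlated pair kept
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 4))
  expect_gte(g@negativeFraction, 1 / 6)
  expect_error(weightedGraph(cbind(t, 0 * t)), "region 2")

  # on coupled synthetic data negative correlations are the exception
  cfg <- syntheticConfig(gridDims = c(4, 4, 3), nTrueRegions = 6,
                         nControls = 4, nPatients = 0, nTimepoints = 177,
                         backgroundCoupling = 0.3, seed = 10)
  sim <- generateCohort(cfg)
  labs <- regionLabels(sim$truth)
  atlas <- new("VoxelAtlas", voxelRegionLabels = labs, nRegions = 6L,
               coords = voxelCoords(sim$truth))
  negs <- vapply(sim$datasets, function(d)
    weightedGraph(regionTimeSeries(d, atlas))@negativeFraction, numeric(1))
  expect_lt(mean(negs), 0.2)
})

test_that("density binarization keeps exactly floor(d * K(K-1)/2) edges", {
  set.seed(2)
  for (K in c(90, 100)) {
    W <- matrix(0, K, K)
    W[upper.tri(W)] <- runif(K * (K - 1) / 2)
    W <- W + t(W)
    g <- new("SubjectGraph", weights = W, binary = matrix(numeric(0), 0, 0),
             densityTarget = NA_real_, communities = integer(),
             negativeFraction = 0, subjectId = "x")
    b <- binarizeDensity(g, 0.30)
    edges <- sum(binaryMatrix(b)[upper.tri(W)])
    expect_equal(edges, if (K == 90) 1201 else 1485)
    # kept edges are the strongest ones
    expect_gte(min(W[binaryMatrix(b) == 1]),
               max(W[binaryMatrix(b) == 0 & upper.tri(W)]))
  }

  # all-equal weights: ties resolved to the lexicographically first pairs
  K <- 6
  W <- matrix(1, K, K); diag(W) <- 0
  g <- graphFromBinary(matrix(0, K, K))
  g@weights <- W
  b <- binarizeDensity(g, 0.30)   # floor(0.3 * 15) = 4 edges
  kept <- which(binaryMatrix(b) == 1 & upper.tri(W), arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), ]
  expect_equal(unname(kept), rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
})

test_that("community detection is deterministic and modularity-consistent", {
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- 1; B[4:6, 4:6] <- 1; diag(B) <- 0
  g <- graphFromBinary(B)
  g1 <- detectCommunities(g, seed = 7)
  g2 <- detectCommunities(g, seed = 7)
  expect_identical(communities(g1), communities(g2))
  expect_identical(length(unique(communities(g1))), 2L)
  expect_true(samePartition(communities(g1), c(1, 1, 1, 2, 2, 2)))

  set.seed(3)
  W <- matrix(runif(64), 8, 8); W <- (W + t(W)) / 2; diag(W) <- 0
  gw <- new("SubjectGraph", weights = W, binary = matrix(numeric(0), 0, 0),
            densityTarget = NA_real_, communities = integer(),
            negativeFraction = 0, subjectId = "w")
  gw <- detectCommunities(gw, seed = 1)
  q <- graphModularity(gw)
  expect_equal(q, modularityOracle(W, communities(gw)), tolerance = 1e-12)
  singleton <- modularityOracle(W, seq_len(8))
  expect_gte(q, singleton)
})

test_that("pair and node measures agree with enumeration oracles", {
  set.seed(4)
  graphs <- c(allGraphs(4),
              lapply(1:30, function(i) randomBinaryGraph(6, 0.4)),
              lapply(1:10, function(i) randomBinaryGraph(8, 0.35)))
  for (B in graphs) {
    g <- graphFromBinary(B)
    expect_equal(pairDistance(g), bfsDistanceOracle(B))
    expect_equal(pairMatchingIndex(g, "jaccard"), matchingOracle(B, "jaccard"))
    expect_equal(pairMatchingIndex(g, "bct"), matchingOracle(B, "bct"))
    expect_equal(pairGtom(g, 2L), gtomOracle(B, 2))
    cc <- fcnetclass:::nodeClustering(g)
    expect_equal(cc, clusteringOracle(B))
    bw <- as.numeric(igraph::betweenness(
      igraph::graph_from_adjacency_matrix(B, mode = "undirected"),
      directed = FALSE))
    expect_equal(bw, betweennessOracle(B), tolerance = 1e-9)
  }
})

test_that("matching index and GTOM boundary values behave as defined", {
  # two nodes with identical neighbor profiles (excluding each other)
  B <- matrix(0, 5, 5)
  B[1, 3:5] <- 1; B[2, 3:5] <- 1
  B <- B + t(B)
  g <- graphFromBinary(B)
  expect_equal(pairMatchingIndex(g)[1, 2], 1)
  # disjoint neighbor sets
  B2 <- matrix(0, 6, 6)
  B2[1, 3] <- 1; B2[2, 4] <- 1
  B2 <- B2 + t(B2)
  expect_equal(pairMatchingIndex(graphFromBinary(B2))[1, 2], 0)
  # isolated pair has GTOM 0; a connected graph at large m reaches 1
  expect_equal(pairGtom(graphFromBinary(B2), 2L)[5, 6], 0)
  # saturated neighborhoods: m large enough that everyone reaches everyone.
  # Adjacent pairs hit the maximum 1; non-adjacent pairs saturate at
  # (K-2)/K because the adjacency correction only credits direct edges.
  K <- 5
  ring <- matrix(0, K, K)
  for (i in seq_len(K)) ring[i, i %% K + 1] <- 1
  ring <- ring + t(ring)
  G <- pairGtom(graphFromBinary(ring), 10L)
  up <- upper.tri(G)
  expect_true(all(G[up & ring == 1] == 1))
  expect_true(all(G[up & ring == 0] == (K - 2) / K))
})

test_that("registry values on canonical graphs are correct", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  g <- detectCommunities(graphFromBinary(tri), 1)
  reg <- measureRegistry(g)
  expect_equal(unname(reg$node$clustering), c(1, 1, 1))
  expect_equal(unname(reg$global["transitivity"]), 1)

  K <- 7
  star <- matrix(0, K, K); star[1, 2:K] <- 1; star <- star + t(star)
  gs <- detectCommunities(graphFromBinary(star), 1)
  regs <- measureRegistry(gs)
  expect_equal(unname(regs$node$degree[1]), K - 1)
  expect_equal(unname(regs$node$degree[-1]), rep(1, K - 1))

  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- 1
  path <- path + t(path)
  gp <- detectCommunities(graphFromBinary(path), 1)
  regp <- measureRegistry(gp)
  D <- bfsDistanceOracle(path)
  expect_equal(unname(regp$global["characteristicPathLength"]),
               mean(D[upper.tri(D)]))
  expect_equal(unname(regp$global["density"]), 4 / 10)
})

test_that("measures are equivariant under node relabeling", {
  set.seed(5)
  for (rep in 1:5) {
    B <- randomBinaryGraph(7, 0.4)
    perm <- sample(7)
    Bp <- B[perm, perm]
    for (fn in list(pairDistance, pairMatchingIndex, pairGtom,
                    pairNeighborhoodOverlap)) {
      M <- fn(graphFromBinary(B))
      Mp <- fn(graphFromBinary(Bp))
      expect_equal(Mp, M[perm, perm])
    }
  }
})

featureGraphs <- function(Bs) {
  lapply(seq_along(Bs), function(i)
    detectCommunities(graphFromBinary(Bs[[i]]), 1))
}

test_that("feature blocks have K + 2 and K(K-1)/2 + 2 columns", {
  set.seed(6)
  K <- 90
  W <- matrix(0, K, K); W[upper.tri(W)] <- runif(K * (K - 1) / 2)
  W <- W + t(W)
  g <- new("SubjectGraph", weights = W, binary = matrix(numeric(0), 0, 0),
           densityTarget = NA_real_, communities = integer(),
           negativeFraction = 0, subjectId = "S1")
  g <- detectCommunities(binarizeDensity(g, 1), 1)   # fully connected binary
  ftNode <- assembleFeatures(list(g), "S1",
    config = list(nodeMeasures = "degree", pairMeasures = character(),
                  globalMeasures = character()))
  expect_identical(ncol(featureMatrix(ftNode)), 92L)
  ftPair <- assembleFeatures(list(g), "S1",
    config = list(nodeMeasures = character(), pairMeasures = "distance",
                  globalMeasures = character()))
  expect_identical(ncol(featureMatrix(ftPair)), 4007L)
})

test_that("non-finite features are dropped table-wide and recorded", {
  B1 <- matrix(0, 5, 5)
  for (i in 1:4) B1[i, i + 1] <- 1
  B1 <- B1 + t(B1)                      # connected path
  B2 <- B1
  B2[4, 5] <- B2[5, 4] <- 0             # node 5 isolated for subject 2
  gs <- featureGraphs(list(B1, B2))
  ft <- assembleFeatures(gs, c("A", "B"),
    config = list(nodeMeasures = "degree", pairMeasures = "distance",
                  globalMeasures = character()))
  expect_true(all(is.finite(featureMatrix(ft))))
  # every pair involving node 5 is unreachable for subject B -> dropped
  expect_true(all(sprintf("distance_p%d_5", 1:4) %in% droppedFeatures(ft)))
  expect_false(any(droppedFeatures(ft) %in% featureCatalog(ft)$featureId)[1])
  # the finite pairs survive for both subjects
  expect_true("distance_p1_2" %in% featureCatalog(ft)$featureId)

  expect_error(assembleFeatures(c(gs, featureGraphs(list(matrix(0, 3, 3)))[1])),
               "different number of regions")
})
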