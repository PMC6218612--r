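lineDataset <- function(series, id = "S1") {
  new("VoxelDataset", subjectId = id, sessionId = "ses1",
      groupLabel = "control", coords = cbind(seq_len(ncol(series)), 1L, 1L),
      series = series)
}

test_that("group concatenation stacks series in input order", {
  set.seed(1)
  a <- lineDataset(matrix(rnorm(177 * 4), 177, 4), "A")
  b <- lineDataset(matrix(rnorm(177 * 4), 177, 4), "B")
  one <- concatenateGroup(list(a))
  expect_identical(seriesMatrix(one), seriesMatrix(a))
  two <- concatenateGroup(list(a, b))
  expect_identical(nrow(seriesMatrix(two)), 354L)
  expect_identical(seriesMatrix(two)[1:177, ], seriesMatrix(a))
  expect_identical(seriesMatrix(two)[178:354, ], seriesMatrix(b))

  # concatenation order permutes rows only: correlations are unchanged
  swapped <- concatenateGroup(list(b, a))
  expect_equal(correlationMatrix(seriesMatrix(swapped)),
               correlationMatrix(seriesMatrix(two)), tolerance = 1e-12)

  bad <- lineDataset(matrix(rnorm(177 * 4), 177, 4))
  bad@coords[2, 1] <- 99L
  expect_error(concatenateGroup(list(a, bad)), "voxel 2")
})

test_that("correlation matrix matches the scalar Pearson oracle", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  C <- correlationMatrix(x)
  for (i in 1:3) for (j in 1:3)
    expect_equal(C[i, j], if (i == j) 1 else pearsonOracle(x[, i], x[, j]),
                 tolerance = 1e-12)

  dup <- cbind(x, x[, 1])
  expect_equal(correlationMatrix(dup)[1, 4], 1)
  neg <- cbind(x, -x[, 2])
  expect_equal(correlationMatrix(neg)[2, 4], -1)

  x[, 2] <- 5
  expect_error(correlationMatrix(x), "voxel 2")
  expect_error(correlationMatrix(matrix(rnorm(40), 2, 20), maxVoxels = 10),
               "downsample")
})

test_that("correlation distance maps r = 1, 0, -1 to 0, 1, 2", {
  C <- matrix(c(1, 1, 0, -1,
                1, 1, 0, -1,
                0, 0, 1, 0,
                -1, -1, 0, 1), 4, 4)
  D <- correlationDistance(C)
  expect_equal(diag(D), rep(0, 4))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  expect_equal(D[1, 4], 2)
  expect_true(all(D >= 0 & D <= 2))
})

test_that("two distant identical blobs merge last on a chain", {
  vals <- c(0, 0, 0, 10, 10, 10)
  D <- as.matrix(stats::dist(vals))
  coords <- cbind(seq_along(vals), 1L, 1L)
  dend <- constrainedWard(D, coords, 6L)
  expect_identical(dend@nLeaves, 6L)
  # the final merge joins the two blobs; the 2-cut is exactly them
  atlas <- cutDendrogram(dend, 2L)
  expect_true(samePartition(regionLabels(atlas), c(1, 1, 1, 2, 2, 2)))
  expect_equal(max(dend@heights), dend@heights[5])
})

test_that("constrained 2-cut on a line equals the exhaustive contiguous optimum", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    cut0 <- sample(2:(n - 1), 1)
    vals <- c(rnorm(cut0, 0, 0.3), rnorm(n - cut0, 4, 0.3))
    D <- as.matrix(stats::dist(vals))
    coords <- cbind(seq_len(n), 1L, 1L)
    atlas <- cutDendrogram(constrainedWard(D, coords, 6L), 2L)
    # exhaustive search over all contiguous bipartitions of the line
    objs <- vapply(seq_len(n - 1), function(k)
      wardObjectiveOracle(vals, rep(1:2, c(k, n - k))), numeric(1))
    bestK <- which.min(objs)
    expect_true(samePartition(regionLabels(atlas),
                              rep(1:2, c(bestK, n - bestK))))
  }
})

test_that("with full adjacency constrained Ward reproduces hclust ward.D2", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 12
    pts <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(stats::dist(pts))
    coords <- cbind(seq_len(n), 1L, 1L)
    dend <- constrainedWard(D, coords, connectivity = "full")
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
    expect_equal(sort(dend@heights), sort(hc$height), tolerance = 1e-8)
    for (K in c(2, 4, 7)) {
      mine <- regionLabels(cutDendrogram(dend, K))
      theirs <- stats::cutree(hc, K)
      expect_identical(length(unique(paste(mine, theirs))), as.integer(K))
    }
  }
})

test_that("voxel input order does not change the partitions", {
  set.seed(5)
  cfg <- syntheticConfig(gridDims = c(4, 4, 2), nTrueRegions = 3,
                         nControls = 2, nPatients = 0, nTimepoints = 40,
                         seed = 15)
  grp <- concatenateGroup(generateCohort(cfg)$datasets)
  D <- correlationDistance(correlationMatrix(seriesMatrix(grp)))
  coords <- voxelCoords(grp)
  dend <- constrainedWard(D, coords, 6L)
  perm <- sample(nrow(coords))
  dendP <- constrainedWard(D[perm, perm], coords[perm, , drop = FALSE], 6L)
  for (K in c(2, 3, 5)) {
    lab <- regionLabels(cutDendrogram(dend, K))
    labP <- regionLabels(cutDendrogram(dendP, K))
    # same partition after undoing the permutation
    expect_identical(length(unique(paste(lab[perm], labP))), as.integer(K))
  }
})

test_that("a disconnected voxel graph is rejected before clustering", {
  coords <- rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(10L, 1L, 1L))
  D <- as.matrix(stats::dist(c(0, 1, 2)))
  expect_error(constrainedWard(D, coords, 6L), "disconnected")
})

test_that("dendrogram cuts partition the voxels and stay contiguous", {
  cfg <- syntheticConfig(gridDims = c(4, 3, 3), nTrueRegions = 4,
                         nControls = 1, nPatients = 1, nTimepoints = 30,
                         seed = 44)
  grp <- concatenateGroup(generateCohort(cfg)$datasets)
  D <- correlationDistance(correlationMatrix(seriesMatrix(grp)))
  dend <- constrainedWard(D, voxelCoords(grp), 6L)
  n <- dend@nLeaves
  expect_identical(regionLabels(cutDendrogram(dend, n)), seq_len(n))
  expect_identical(regionLabels(cutDendrogram(dend, 1L)), rep(1L, n))
  expect_error(cutDendrogram(dend, 0L), "K must lie")
  for (K in c(2L, 5L, 11L)) {
    atlas <- cutDendrogram(dend, K)
    labs <- regionLabels(atlas)
    expect_identical(sum(tabulate(labs, K)), n)
    for (r in seq_len(K))
      expect_true(fcnetclass:::voxelGraphConnected(
        voxelCoords(atlas)[labs == r, , drop = FALSE], 6L))
  }
})

test_that("overlap report matches direct voxel counting", {
  coords <- gridAtlasCoords <- cbind(rep(1:4, each = 2), rep(1:2, 4), 1L)
  a <- new("VoxelAtlas", voxelRegionLabels = rep(1:2, each = 4L),
           nRegions = 2L, coords = coords)
  self <- atlasOverlapReport(a, a)
  expect_equal(self$percentOverlap, c(100, 100))
  b <- new("VoxelAtlas", voxelRegionLabels = rep(c(1L, 2L), 4L),
           nRegions = 2L, coords = coords)
  half <- atlasOverlapReport(a, b)
  expect_equal(half$percentOverlap, rep(50, 4))

  set.seed(6)
  ra <- new("VoxelAtlas", voxelRegionLabels = sample(1:3, 8, TRUE) |>
              (\(x) as.integer(factor(x)))(), nRegions = 3L, coords = coords)
  ra@nRegions <- max(ra@voxelRegionLabels)
  rep1 <- atlasOverlapReport(ra, b)
  for (k in seq_len(nrow(rep1))) {
    r <- rep1$region[k]; l <- rep1$referenceLabel[k]
    expect_equal(rep1$percentOverlap[k],
                 100 * sum(ra@voxelRegionLabels == r &
                           b@voxelRegionLabels == l) /
                   sum(ra@voxelRegionLabels == r))
  }
  expect_error(atlasOverlapReport(a, new("VoxelAtlas",
    voxelRegionLabels = 1L, nRegions = 1L,
    coords = cbind(1L, 1L, 1L))), "grid")
})
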