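#' @import methods
NULL

#' Configuration for the synthetic resting-state cohort generator
#'
#' Describes a synthetic cohort: a 3D voxel grid partitioned into spatially
#' contiguous "true" regions whose voxels share a latent autocorrelated
#' (AR(1)) time course, two subject groups (controls and patients) whose
#' latent signals are coupled according to a region-by-region correlation
#' matrix, and planted group differences in the coupling of designated
#' region pairs. Use [syntheticConfig()] to construct validated objects.
#'
#' @slot gridDims integer(3), voxels per axis.
#' @slot nTrueRegions integer, number of contiguous latent regions.
#' @slot nTimepoints integer, time points per session (default 177).
#' @slot trSeconds numeric, sampling interval in seconds (default 2).
#' @slot nControls,nPatients integer group sizes.
#' @slot arCoefficient numeric in (-1, 1), lag-1 autocorrelation of the
#'   latent region signals.
#' @slot baseCoupling numeric matrix, region-by-region latent correlation
#'   (symmetric, unit diagonal, positive semidefinite).
#' @slot plantedEffects data.frame with columns `regionA`, `regionB`,
#'   `delta`: coupling changes applied to the patient group only.
#' @slot voxelNoiseSd numeric, sd of iid voxel-level measurement noise.
#' @slot sessionStateSd numeric, sd of the session-specific perturbation of
#'   the coupling matrix used by [generateSessionPair()].
#' @slot bandHz numeric(2) or length 0; optional band limits (Hz) applied to
#'   the latent signals (off by default).
#' @slot seed integer RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    gridDims = "integer",
    nTrueRegions = "integer",
    nTimepoints = "integer",
    trSeconds = "numeric",
    nControls = "integer",
    nPatients = "integer",
    arCoefficient = "numeric",
    baseCoupling = "matrix",
    plantedEffects = "data.frame",
    voxelNoiseSd = "numeric",
    sessionStateSd = "numeric",
    bandHz = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
    msg <- c(msg, "gridDims must be three positive integers")
  R <- object@nTrueRegions
  if (R < 1L) msg <- c(msg, "nTrueRegions must be >= 1")
  if (R > prod(object@gridDims))
    msg <- c(msg, "nTrueRegions exceeds the number of voxels")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (abs(object@arCoefficient) >= 1)
    msg <- c(msg, "arCoefficient must lie in (-1, 1)")
  C <- object@baseCoupling
  if (!is.numeric(C) || nrow(C) != R || ncol(C) != R) {
    msg <- c(msg, "baseCoupling must be an nTrueRegions x nTrueRegions matrix")
  } else {
    if (max(abs(C - t(C))) > 1e-8) msg <- c(msg, "baseCoupling must be symmetric")
    if (max(abs(diag(C) - 1)) > 1e-8)
      msg <- c(msg, "baseCoupling must have unit diagonal")
    if (any(abs(C) > 1 + 1e-8))
      msg <- c(msg, "baseCoupling entries must lie in [-1, 1]")
  }
  pe <- object@plantedEffects
  if (nrow(pe) > 0) {
    if (!all(c("regionA", "regionB", "delta") %in% names(pe)))
      msg <- c(msg, "plantedEffects needs columns regionA, regionB, delta")
    else if (any(pe$regionA < 1 | pe$regionA > R | pe$regionB < 1 |
                 pe$regionB > R | pe$regionA == pe$regionB))
      msg <- c(msg, "plantedEffects region indices out of range")
  }
  if (object@voxelNoiseSd < 0) msg <- c(msg, "voxelNoiseSd must be >= 0")
  if (object@sessionStateSd < 0) msg <- c(msg, "sessionStateSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One subject-session's voxel time series
#'
#' Holds a time-by-voxel matrix together with the integer 3D coordinates of
#' each voxel and subject/session metadata.
#'
#' @slot subjectId,sessionId character scalars.
#' @slot groupLabel `"control"` or `"patient"`.
#' @slot coords integer matrix, voxels x 3.
#' @slot series numeric matrix, time x voxels.
#' @exportClass VoxelDataset
setClass("VoxelDataset",
  representation(
    subjectId = "character",
    sessionId = "character",
    groupLabel = "character",
    coords = "matrix",
    series = "matrix"
  )
)

setValidity("VoxelDataset", function(object) {
  msg <- character()
  if (!object@groupLabel %in% c("control", "patient"))
    msg <- c(msg, "groupLabel must be 'control' or 'patient'")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (nrow(object@coords) != ncol(object@series))
    msg <- c(msg, "number of coords must equal number of series columns")
  if (anyDuplicated(object@coords)) msg <- c(msg, "coords must be unique")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' @slot voxelRegionLabels integer vector, true region per voxel.
#' @slot plantedPairs data.frame (`regionA`, `regionB`, `delta`).
#' @slot coords integer voxel coordinate matrix the labels refer to.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    voxelRegionLabels = "integer",
    plantedPairs = "data.frame",
    coords = "matrix"
  )
)

#' Merge history of constrained agglomerative clustering
#'
#' Records the full sequence of merges produced by [constrainedWard()].
#' Cluster ids follow the usual agglomerative convention: leaves are
#' 1..nLeaves and the cluster created at step s has id nLeaves + s. Merge
#' heights are recorded as produced; under a spatial constraint Ward heights
#' are not guaranteed monotone and no monotonicity is asserted.
#'
#' @slot merges integer matrix (nLeaves-1) x 2 of merged cluster ids.
#' @slot heights numeric merge heights.
#' @slot nLeaves integer number of leaves.
#' @slot coords voxel coordinates of the leaves.
#' @exportClass WardDendrogram
setClass("WardDendrogram",
  representation(
    merges = "matrix",
    heights = "numeric",
    nLeaves = "integer",
    coords = "matrix"
  )
)

setValidity("WardDendrogram", function(object) {
  msg <- character()
  if (nrow(object@merges) != object@nLeaves - 1L)
    msg <- c(msg, "a fully merged tree needs nLeaves - 1 merges")
  if (length(object@heights) != nrow(object@merges))
    msg <- c(msg, "one height per merge required")
  if (any(object@heights < -1e-12)) msg <- c(msg, "heights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' A voxel-to-region parcellation (atlas)
#'
#' @slot voxelRegionLabels integer region label per voxel, in 1..nRegions.
#' @slot nRegions integer number of regions.
#' @slot coords integer voxel coordinate matrix.
#' @exportClass VoxelAtlas
setClass("VoxelAtlas",
  representation(
    voxelRegionLabels = "integer",
    nRegions = "integer",
    coords = "matrix"
  )
)

setValidity("VoxelAtlas", function(object) {
  msg <- character()
  lab <- object@voxelRegionLabels
  K <- object@nRegions
  if (length(lab) != nrow(object@coords))
    msg <- c(msg, "one label per voxel required")
  if (length(lab) && (!all(lab >= 1L & lab <= K) ||
      !all(seq_len(K) %in% lab)))
    msg <- c(msg, "labels must cover 1..nRegions with no empty region")
  if (length(msg)) msg else TRUE
})

#' Per-subject region graph
#'
#' Weighted adjacency (nonnegative correlation weights, zero diagonal), the
#' density-thresholded binary adjacency, and the community partition used by
#' module-aware measures.
#'
#' @slot weights numeric K x K symmetric matrix, zero diagonal.
#' @slot binary numeric K x K 0/1 matrix (empty until [binarizeDensity()]).
#' @slot densityTarget numeric in (0, 1]; NA until binarized.
#' @slot communities integer length-K partition (empty until
#'   [detectCommunities()]).
#' @slot negativeFraction numeric, fraction of off-diagonal correlations that
#'   were negative and therefore zeroed.
#' @slot subjectId character.
#' @exportClass SubjectGraph
setClass("SubjectGraph",
  representation(
    weights = "matrix",
    binary = "matrix",
    densityTarget = "numeric",
    communities = "integer",
    negativeFraction = "numeric",
    subjectId = "character"
  )
)

setValidity("SubjectGraph", function(object) {
  msg <- character()
  W <- object@weights
  if (nrow(W) != ncol(W)) msg <- c(msg, "weights must be square")
  if (any(W < 0)) msg <- c(msg, "weights must be nonnegative")
  if (any(diag(W) != 0)) msg <- c(msg, "weights diagonal must be zero")
  if (max(abs(W - t(W))) > 1e-10) msg <- c(msg, "weights must be symmetric")
  B <- object@binary
  if (length(B)) {
    if (!all(B %in% c(0, 1))) msg <- c(msg, "binary entries must be 0/1")
    if (any(diag(B) != 0)) msg <- c(msg, "binary diagonal must be zero")
    K <- nrow(W)
    if (!is.na(object@densityTarget)) {
      want <- floor(object@densityTarget * K * (K - 1) / 2)
      if (sum(B[upper.tri(B)]) != want)
        msg <- c(msg, "binary edge count must equal floor(density * K(K-1)/2)")
    }
  }
  if (length(object@communities) &&
      length(object@communities) != nrow(W))
    msg <- c(msg, "communities must have one label per node")
  if (length(msg)) msg else TRUE
})

#' Catalog of assembled network features
#'
#' One row per feature column of a [FeatureTable-class]: the measure it came
#' from, its scope (`node`, `pair`, `global`, `mean`, `sd`) and the node
#' indices involved (NA where not applicable).
#'
#' @slot entries data.frame with columns `featureId`, `measure`, `scope`,
#'   `nodeA`, `nodeB`.
#' @exportClass FeatureCatalog
setClass("FeatureCatalog", representation(entries = "data.frame"))

setValidity("FeatureCatalog", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("featureId", "measure", "scope", "nodeA", "nodeB")
  if (!all(need %in% names(e)))
    msg <- c(msg, "entries must have featureId, measure, scope, nodeA, nodeB")
  else if (anyDuplicated(e$featureId)) msg <- c(msg, "featureIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Subjects-by-features matrix with provenance
#'
#' @slot matrix numeric subjects x features matrix, all finite.
#' @slot subjects character subject ids (row order).
#' @slot catalog [FeatureCatalog-class] of the retained columns.
#' @slot dropped character ids of features excluded because they were
#'   non-finite for at least one subject.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(
    matrix = "matrix",
    subjects = "character",
    catalog = "FeatureCatalog",
    dropped = "character"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@subjects) != nrow(object@matrix))
    msg <- c(msg, "one subject per matrix row required")
  if (length(object@matrix) && !all(is.finite(object@matrix)))
    msg <- c(msg, "retained feature matrix must be all finite")
  if (ncol(object@matrix) != nrow(object@catalog@entries))
    msg <- c(msg, "catalog must describe every retained column")
  if (length(msg)) msg else TRUE
})

#' Nested cross-validation plan
#'
#' Outer fold assignments for every random partition and the rotation of
#' inner train/validation folds within each outer training set. Deterministic
#' given the seed.
#'
#' @slot subjects character subject ids.
#' @slot labels factor of group labels (levels control, patient).
#' @slot nOuterFolds,nInnerFolds,nPartitions integers.
#' @slot seed integer.
#' @slot outerFolds list (one integer vector per partition): outer fold of
#'   each subject.
#' @slot innerFolds nested list `[[partition]][[fold]]`: inner fold of each
#'   non-test subject, named by subject id.
#' @exportClass CVPlan
setClass("CVPlan",
  representation(
    subjects = "character",
    labels = "factor",
    nOuterFolds = "integer",
    nInnerFolds = "integer",
    nPartitions = "integer",
    seed = "integer",
    outerFolds = "list",
    innerFolds = "list"
  )
)

setValidity("CVPlan", function(object) {
  msg <- character()
  n <- length(object@subjects)
  if (length(object@labels) != n) msg <- c(msg, "one label per subject required")
  if (length(object@outerFolds) != object@nPartitions)
    msg <- c(msg, "one outer fold assignment per partition required")
  for (p in seq_along(object@outerFolds)) {
    f <- object@outerFolds[[p]]
    if (length(f) != n || !all(f %in% seq_len(object@nOuterFolds))) {
      msg <- c(msg, "every subject must sit in exactly one outer fold")
      break
    }
    sizes <- tabulate(f, object@nOuterFolds)
    if (max(sizes) - min(sizes) > 1L) {
      msg <- c(msg, "outer folds must be equal-sized up to the remainder")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Results of a double cross-validation run
#'
#' @slot traces list of per-(partition, fold) selection traces. Each trace is
#'   a list with elements `partition`, `fold`, `screened`, `screenAccuracy`,
#'   `sfsOrder`, `innerAccuracyByStep`, `testAccuracyByStep`, `bestStep`,
#'   `testSubjects`, `predictions`, `confusion` (tp, tn, fp, fn at bestStep).
#' @slot misclassCounts named integer: times each subject was misclassified
#'   at its fold's best step.
#' @slot nPartitions integer (the denominator of the misclassification rate).
#' @slot curves data.frame `step`, `singleCV`, `doubleCV`: accuracy versus
#'   number of selected features averaged over traces.
#' @slot summary list with pooled `accuracy`, `sensitivity`, `specificity`.
#' @slot labels factor of true labels, named by subject.
#' @exportClass RunResults
setClass("RunResults",
  representation(
    traces = "list",
    misclassCounts = "integer",
    nPartitions = "integer",
    curves = "data.frame",
    summary = "list",
    labels = "factor"
  )
)
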