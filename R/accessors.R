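#' @name accessors
#' @title Accessors for fcnetclass objects
#' @description Accessor generics for the core classes: time series,
#'   coordinates, labels, graph matrices, feature matrices and catalogs.
#' @param object an fcnetclass S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(object) standardGeneric("seriesMatrix"))
#' @rdname accessors
#' @export
setMethod("seriesMatrix", "VoxelDataset", function(object) object@series)

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setMethod("voxelCoords", "VoxelDataset", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("voxelCoords", "VoxelAtlas", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("voxelCoords", "GroundTruth", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "VoxelDataset", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("sessionId", function(object) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setMethod("sessionId", "VoxelDataset", function(object) object@sessionId)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "VoxelDataset", function(object) object@groupLabel)

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "VoxelAtlas", function(object) object@voxelRegionLabels)
#' @rdname accessors
#' @export
setMethod("regionLabels", "GroundTruth", function(object) object@voxelRegionLabels)

#' @rdname accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setMethod("nRegions", "VoxelAtlas", function(object) object@nRegions)

#' @rdname accessors
#' @export
setGeneric("weightsMatrix", function(object) standardGeneric("weightsMatrix"))
#' @rdname accessors
#' @export
setMethod("weightsMatrix", "SubjectGraph", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("binaryMatrix", function(object) standardGeneric("binaryMatrix"))
#' @rdname accessors
#' @export
setMethod("binaryMatrix", "SubjectGraph", function(object) object@binary)

#' @rdname accessors
#' @export
setGeneric("communities", function(object) standardGeneric("communities"))
#' @rdname accessors
#' @export
setMethod("communities", "SubjectGraph", function(object) object@communities)

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("featureCatalog", function(object) standardGeneric("featureCatalog"))
#' @rdname accessors
#' @export
setMethod("featureCatalog", "FeatureTable", function(object) object@catalog@entries)

#' @rdname accessors
#' @export
setGeneric("droppedFeatures", function(object) standardGeneric("droppedFeatures"))
#' @rdname accessors
#' @export
setMethod("droppedFeatures", "FeatureTable", function(object) object@dropped)

#' @rdname accessors
#' @export
setGeneric("cvTraces", function(object) standardGeneric("cvTraces"))
#' @rdname accessors
#' @export
setMethod("cvTraces", "RunResults", function(object) object@traces)

#' @rdname accessors
#' @export
setGeneric("accuracyCurves", function(object) standardGeneric("accuracyCurves"))
#' @rdname accessors
#' @export
setMethod("accuracyCurves", "RunResults", function(object) object@curves)

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", paste(object@gridDims, collapse = "x"), "grid,",
      object@nTrueRegions, "regions,", object@nTimepoints, "timepoints\n")
  cat("  ", object@nControls, "controls /", object@nPatients, "patients;",
      "AR(1) =", object@arCoefficient, "; noise sd =", object@voxelNoiseSd, "\n")
  if (nrow(object@plantedEffects))
    cat("  planted effects on",
        paste(sprintf("(%d,%d): %+.2f", object@plantedEffects$regionA,
                      object@plantedEffects$regionB,
                      object@plantedEffects$delta), collapse = ", "), "\n")
})

setMethod("show", "VoxelDataset", function(object) {
  cat("VoxelDataset", object@subjectId, "/", object@sessionId,
      sprintf("(%s): %d timepoints x %d voxels\n", object@groupLabel,
              nrow(object@series), ncol(object@series)))
})

setMethod("show", "VoxelAtlas", function(object) {
  sizes <- tabulate(object@voxelRegionLabels, object@nRegions)
  cat("VoxelAtlas:", object@nRegions, "regions over",
      length(object@voxelRegionLabels), "voxels",
      sprintf("(region size %d-%d)\n", min(sizes), max(sizes)))
})

setMethod("show", "WardDendrogram", function(object) {
  cat("WardDendrogram:", object@nLeaves, "leaves,",
      nrow(object@merges), "merges\n")
})

setMethod("show", "SubjectGraph", function(object) {
  K <- nrow(object@weights)
  cat("SubjectGraph", object@subjectId, ":", K, "nodes")
  if (length(object@binary))
    cat(sprintf(", %d binary edges (density target %.0f%%)",
                sum(object@binary[upper.tri(object@binary)]),
                100 * object@densityTarget))
  if (length(object@communities))
    cat(",", length(unique(object@communities)), "communities")
  cat("\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@matrix), "subjects x",
      ncol(object@matrix), "features;", length(object@dropped),
      "dropped as non-finite\n")
})

setMethod("show", "CVPlan", function(object) {
  cat("CVPlan:", length(object@subjects), "subjects,",
      object@nPartitions, "partitions x", object@nOuterFolds,
      "outer folds,", object@nInnerFolds, "inner folds\n")
})

setMethod("show", "RunResults", function(object) {
  cat("RunResults:", length(object@traces), "fold traces;",
      sprintf("pooled accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              object@summary$accuracy, object@summary$sensitivity,
              object@summary$specificity))
})
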