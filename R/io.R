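#' Write a voxel dataset to disk
#'
#' Serialises a [VoxelDataset-class] as a NIfTI pair plus a CSV sidecar:
#' `<prefix>_bold.nii.gz` holds the 4D volume (x, y, z, time; voxels outside
#' the dataset's coordinate set are zero), `<prefix>_mask.nii.gz` marks the
#' included voxels, and `<prefix>_meta.csv` carries subject id, session id,
#' group label and dimensions. The round trip through [readDataset()] is
#' lossless up to single-precision NIfTI storage; pass `datatype = "double"`
#' for an exact round trip.
#'
#' @param dataset a [VoxelDataset-class].
#' @param prefix file path prefix (directories must exist).
#' @param datatype NIfTI storage type, default `"double"`.
#' @return `prefix`, invisibly.
#' @export
writeDataset <- function(dataset, prefix, datatype = "double") {
  stopifnot(is(dataset, "VoxelDataset"))
  dims <- apply(dataset@coords, 2L, max)
  Tn <- nrow(dataset@series)
  vol <- array(0, dim = c(dims, Tn))
  mask <- array(0L, dim = dims)
  for (v in seq_len(nrow(dataset@coords))) {
    xyz <- dataset@coords[v, ]
    vol[xyz[1], xyz[2], xyz[3], ] <- dataset@series[, v]
    mask[xyz[1], xyz[2], xyz[3]] <- 1L
  }
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = datatype),
                     paste0(prefix, "_bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(mask, datatype = "int16"),
                     paste0(prefix, "_mask.nii.gz"))
  meta <- data.frame(subject_id = dataset@subjectId,
                     session_id = dataset@sessionId,
                     group = dataset@groupLabel,
                     n_timepoints = Tn,
                     n_voxels = nrow(dataset@coords))
  utils::write.csv(meta, paste0(prefix, "_meta.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a voxel dataset written by [writeDataset()]
#'
#' @param prefix the file path prefix used when writing.
#' @return a [VoxelDataset-class].
#' @export
readDataset <- function(prefix) {
  metaPath <- paste0(prefix, "_meta.csv")
  if (!file.exists(metaPath)) stop("missing metadata file: ", metaPath)
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  for (field in c("subject_id", "session_id", "group", "n_timepoints", "n_voxels"))
    if (!field %in% names(meta) || is.na(meta[[field]][1]))
      stop("metadata field missing or empty: ", field)
  vol <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  if (length(dim(vol)) != 4L) stop("bold volume is not 4D: field series")
  idx <- which(mask != 0, arr.ind = TRUE)
  # canonical grid ordering (x fastest)
  idx <- idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
  Tn <- dim(vol)[4]
  if (Tn != meta$n_timepoints[1])
    stop("time dimension mismatch with metadata: field n_timepoints")
  if (nrow(idx) != meta$n_voxels[1])
    stop("voxel count mismatch with metadata: field n_voxels")
  series <- matrix(0, Tn, nrow(idx))
  for (v in seq_len(nrow(idx)))
    series[, v] <- vol[idx[v, 1], idx[v, 2], idx[v, 3], ]
  coords <- idx
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"
  new("VoxelDataset",
      subjectId = as.character(meta$subject_id[1]),
      sessionId = as.character(meta$session_id[1]),
      groupLabel = as.character(meta$group[1]),
      coords = coords, series = series)
}

#' Export an atlas as a NIfTI integer label volume
#'
#' @param atlas a [VoxelAtlas-class].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "VoxelAtlas"))
  dims <- apply(atlas@coords, 2L, max)
  vol <- array(0L, dim = dims)
  for (v in seq_len(nrow(atlas@coords))) {
    xyz <- atlas@coords[v, ]
    vol[xyz[1], xyz[2], xyz[3]] <- atlas@voxelRegionLabels[v]
  }
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "int32"), path)
  invisible(path)
}

#' Import an atlas from a NIfTI integer label volume
#'
#' Voxels with label 0 are treated as outside the atlas. Labels are
#' renumbered densely to 1..K preserving order.
#'
#' @param path a NIfTI label volume.
#' @return a [VoxelAtlas-class].
#' @export
readAtlas <- function(path) {
  vol <- RNifti::readNifti(path)
  if (length(dim(vol)) != 3L) stop("label volume must be 3D")
  idx <- which(vol != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
  labs <- vol[idx]
  dense <- as.integer(factor(labs, levels = sort(unique(labs))))
  coords <- idx
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"
  new("VoxelAtlas", voxelRegionLabels = dense,
      nRegions = length(unique(dense)), coords = coords)
}

#' Export a dendrogram's merge history as CSV
#'
#' @param dendro a [WardDendrogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(dendro, path) {
  df <- data.frame(step = seq_along(dendro@heights),
                   clusterA = dendro@merges[, 1],
                   clusterB = dendro@merges[, 2],
                   height = dendro@heights,
                   newCluster = dendro@nLeaves + seq_along(dendro@heights))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a feature table as CSV
#'
#' First column `subject_id`, remaining columns named by feature id.
#' @param ft a [FeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  df <- data.frame(subject_id = ft@subjects, ft@matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
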