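#' Spectrally prewhiten a single time series
#'
#' Flattens the discrete Fourier magnitude spectrum of `x`: each DFT bin is
#' divided by its own magnitude, so the power spectrum of the output is flat
#' (unit magnitude at every retained frequency) and its circular
#' autocorrelation is an impulse. The DFT length is exactly `length(x)`; no
#' zero-padding or tapering is applied, so the transform is a-causal and
#' circular.
#'
#' Bins whose magnitude does not exceed `zeroTol` (relative to the maximum
#' magnitude) are set to zero rather than rescaled, so no energy is injected
#' at frequencies absent from the data. The DC bin is always zeroed: the
#' pipeline's inputs are band-limited and mean-free, and a zero-mean output
#' makes downstream cosine similarity equal the Pearson correlation.
#'
#' @param x numeric vector, length >= 2.
#' @param zeroTol relative magnitude threshold below which bins are zeroed,
#'   default `1e-12`.
#' @return numeric vector of the same length with flat spectrum on the
#'   retained support.
#' @examples
#' y <- prewhitenSeries(sin(seq_len(64)) + rnorm(64))
#' Mod(fft(y))[2:5]  # all (close to) 1
#' @export
prewhitenSeries <- function(x, zeroTol = 1e-12) {
  if (length(x) < 2L) stop("series must have at least 2 time points")
  if (!all(is.finite(x))) stop("series must be finite")
  X <- stats::fft(x)
  mag <- Mod(X)
  if (max(mag) == 0) stop("all-zero series has no spectrum to flatten")
  keep <- mag > zeroTol * max(mag)
  keep[1] <- FALSE                     # DC always removed
  Y <- complex(length(x))
  Y[keep] <- X[keep] / mag[keep]
  Re(stats::fft(Y, inverse = TRUE) / length(x))
}

#' Prewhiten every voxel series of a dataset
#'
#' Applies [prewhitenSeries()] to each column independently; shape, voxel
#' coordinates and metadata are preserved.
#'
#' @param dataset a [VoxelDataset-class].
#' @param zeroTol passed to [prewhitenSeries()].
#' @return a [VoxelDataset-class] of prewhitened series.
#' @export
prewhitenDataset <- function(dataset, zeroTol = 1e-12) {
  stopifnot(is(dataset, "VoxelDataset"))
  out <- dataset@series
  for (v in seq_len(ncol(out))) {
    out[, v] <- tryCatch(prewhitenSeries(dataset@series[, v], zeroTol),
                         error = function(e)
                           stop("voxel ", v, ": ", conditionMessage(e),
                                call. = FALSE))
  }
  initialize(dataset, series = out)
}
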