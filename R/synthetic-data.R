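#' Construct a synthetic cohort configuration
#'
#' Defaults emulate a short resting-state acquisition: 177 time points at a
#' 2-second sampling interval, moderately autocorrelated latent region
#' signals (lag-1 autocorrelation 0.4), weak background coupling between
#' regions and one planted patient-specific coupling deficit.
#'
#' @param gridDims integer(3) voxel grid, default `c(6, 6, 6)`.
#' @param nTrueRegions number of contiguous latent regions, default 8.
#' @param nTimepoints time points per session, default 177.
#' @param trSeconds sampling interval in seconds, default 2.
#' @param nControls,nPatients group sizes, default 10 each.
#' @param arCoefficient lag-1 autocorrelation of latent signals, default 0.4.
#' @param baseCoupling region coupling matrix; default exchangeable with
#'   `backgroundCoupling` off-diagonal, overridden on `basePairs`.
#' @param backgroundCoupling default off-diagonal coupling, default 0.1.
#' @param basePairs optional data.frame (`regionA`, `regionB`, `value`) of
#'   couplings to plant in both groups before patient deltas.
#' @param plantedEffects data.frame (`regionA`, `regionB`, `delta`) of
#'   patient-only coupling changes; default empty.
#' @param voxelNoiseSd voxel measurement noise sd, default 1.
#' @param sessionStateSd sd of session-to-session coupling perturbation,
#'   default 0.1.
#' @param bandHz optional numeric(2) band limits in Hz for the latent
#'   signals; default none.
#' @param seed RNG seed, default 1.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nControls = 2, nPatients = 2,
#'                        plantedEffects = data.frame(regionA = 1, regionB = 2,
#'                                                    delta = -0.2))
#' @export
syntheticConfig <- function(gridDims = c(6L, 6L, 6L), nTrueRegions = 8L,
                            nTimepoints = 177L, trSeconds = 2,
                            nControls = 10L, nPatients = 10L,
                            arCoefficient = 0.4,
                            baseCoupling = NULL, backgroundCoupling = 0.1,
                            basePairs = NULL,
                            plantedEffects = data.frame(regionA = integer(),
                                                        regionB = integer(),
                                                        delta = numeric()),
                            voxelNoiseSd = 1, sessionStateSd = 0.1,
                            bandHz = numeric(), seed = 1L) {
  R <- as.integer(nTrueRegions)
  if (is.null(baseCoupling)) {
    baseCoupling <- matrix(backgroundCoupling, R, R)
    diag(baseCoupling) <- 1
    if (!is.null(basePairs)) {
      for (k in seq_len(nrow(basePairs))) {
        a <- basePairs$regionA[k]; b <- basePairs$regionB[k]
        baseCoupling[a, b] <- baseCoupling[b, a] <- basePairs$value[k]
      }
    }
  }
  cfg <- new("SyntheticConfig",
    gridDims = as.integer(gridDims), nTrueRegions = R,
    nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
    nControls = as.integer(nControls), nPatients = as.integer(nPatients),
    arCoefficient = arCoefficient, baseCoupling = baseCoupling,
    plantedEffects = plantedEffects, voxelNoiseSd = voxelNoiseSd,
    sessionStateSd = sessionStateSd, bandHz = as.numeric(bandHz),
    seed = as.integer(seed))
  # the control coupling must be a feasible correlation matrix, and so must
  # the patient coupling after the planted deltas
  checkCouplingFeasible(baseCoupling, "baseCoupling")
  checkCouplingFeasible(patientCoupling(cfg), "baseCoupling with plantedEffects",
                        pairs = plantedEffects)
  cfg
}

checkCouplingFeasible <- function(C, what, pairs = NULL) {
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    extra <- if (!is.null(pairs) && nrow(pairs))
      paste0(" (planted pairs: ",
             paste(sprintf("(%d,%d)", pairs$regionA, pairs$regionB),
                   collapse = ", "), ")")
    else ""
    stop(what, " is not positive semidefinite", extra, call. = FALSE)
  }
  invisible(TRUE)
}

patientCoupling <- function(config) {
  C <- config@baseCoupling
  pe <- config@plantedEffects
  for (k in seq_len(nrow(pe))) {
    a <- pe$regionA[k]; b <- pe$regionB[k]
    C[a, b] <- C[b, a] <- C[a, b] + pe$delta[k]
  }
  C
}

# Grow nTrueRegions contiguous regions on the grid by breadth-first
# accretion from randomly placed seed voxels under 6-connectivity.
growRegions <- function(coords, nRegions) {
  n <- nrow(coords)
  nbrs <- voxelAdjacency(coords, 6L)
  labels <- integer(n)
  seeds <- sample.int(n, nRegions)
  labels[seeds] <- seq_len(nRegions)
  frontier <- lapply(seeds, function(s) nbrs[[s]])
  remaining <- n - nRegions
  while (remaining > 0L) {
    progressed <- FALSE
    for (r in seq_len(nRegions)) {
      f <- frontier[[r]]
      f <- f[labels[f] == 0L]
      if (!length(f)) { frontier[[r]] <- integer(); next }
      pick <- f[sample.int(length(f), 1L)]
      labels[pick] <- r
      frontier[[r]] <- c(f[f != pick], nbrs[[pick]])
      remaining <- remaining - 1L
      progressed <- TRUE
      if (remaining == 0L) break
    }
    if (!progressed) stop("region growing stalled; grid disconnected?")
  }
  labels
}

# Generate T x R latent region signals: independent unit-variance AR(1)
# columns coupled through the Cholesky-like square root of the coupling
# matrix, so cor(latent_a, latent_b) = C[a, b] in expectation and each
# column keeps lag-1 autocorrelation phi.
latentSignals <- function(Tn, C, phi, bandHz = numeric(), trSeconds = 2) {
  R <- nrow(C)
  innov <- matrix(stats::rnorm(Tn * R), Tn, R)
  z <- apply(innov, 2L, function(e) {
    x <- stats::filter(e, phi, method = "recursive")
    as.numeric(x) * sqrt(1 - phi^2)   # unit stationary variance
  })
  z <- matrix(z, Tn, R)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  L <- z %*% sq
  if (length(bandHz) == 2L) L <- apply(L, 2L, bandLimit, bandHz, trSeconds)
  L
}

# Zero DFT bins outside [low, high] Hz (both tails), keeping the signal real.
bandLimit <- function(x, bandHz, trSeconds) {
  Tn <- length(x)
  f <- (seq_len(Tn) - 1) / (Tn * trSeconds)
  f <- pmin(f, 1 / trSeconds - f)   # fold to [0, Nyquist]
  X <- stats::fft(x)
  X[f < bandHz[1] | f > bandHz[2]] <- 0
  Re(stats::fft(X, inverse = TRUE) / Tn)
}

#' Generate a synthetic multi-subject cohort
#'
#' Voxels of a 3D grid are partitioned into contiguous true regions grown
#' from random seeds; each subject's voxel series is that region's latent
#' AR(1) signal plus independent Gaussian noise. Latent signals are coupled
#' across regions with correlation `baseCoupling` for controls and
#' `baseCoupling` plus the planted deltas for patients. The full generation
#' is deterministic given the config (including its seed).
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `datasets` (list of [VoxelDataset-class], controls then
#'   patients) and `truth` (a [GroundTruth-class]).
#' @export
generateCohort <- function(config) {
  validObject(config)
  Cpat <- patientCoupling(config)
  checkCouplingFeasible(Cpat, "patient coupling", pairs = config@plantedEffects)
  withSeed(config@seed, {
    coords <- gridCoords(config@gridDims)
    storage.mode(coords) <- "integer"
    labels <- growRegions(coords, config@nTrueRegions)
    groups <- c(rep("control", config@nControls), rep("patient", config@nPatients))
    datasets <- vector("list", length(groups))
    for (s in seq_along(groups)) {
      C <- if (groups[s] == "control") config@baseCoupling else Cpat
      L <- latentSignals(config@nTimepoints, C, config@arCoefficient,
                         config@bandHz, config@trSeconds)
      noise <- matrix(stats::rnorm(config@nTimepoints * nrow(coords),
                                   sd = config@voxelNoiseSd),
                      config@nTimepoints, nrow(coords))
      series <- L[, labels, drop = FALSE] + noise
      datasets[[s]] <- new("VoxelDataset",
        subjectId = sprintf("S%03d", s), sessionId = "ses1",
        groupLabel = groups[s], coords = coords, series = series)
    }
    truth <- new("GroundTruth", voxelRegionLabels = labels,
                 plantedPairs = config@plantedEffects, coords = coords)
    list(datasets = datasets, truth = truth)
  })
}

#' Generate a second session for one subject
#'
#' The subject keeps its group's coupling parameters, but the latent signals
#' are re-drawn and the coupling matrix is perturbed with symmetric Gaussian
#' noise of sd `sessionStateSd` (then projected back to a valid correlation
#' matrix), emulating session-specific brain state. With
#' `sessionStateSd = 0` the coupling parameters are identical and only the
#' signal realisation differs.
#'
#' @param config the [SyntheticConfig-class] used to generate the cohort.
#' @param subject a [VoxelDataset-class] from [generateCohort()].
#' @param truth the cohort's [GroundTruth-class].
#' @return a [VoxelDataset-class] with `sessionId = "ses2"`.
#' @export
generateSessionPair <- function(config, subject, truth) {
  stopifnot(is(subject, "VoxelDataset"), is(truth, "GroundTruth"))
  C <- sessionCoupling(config, subject)
  subjIndex <- as.integer(sub("^S", "", subject@subjectId))
  withSeed(deriveSeed(config@seed, 200000L + subjIndex), {
    labels <- truth@voxelRegionLabels
    L <- latentSignals(config@nTimepoints, C, config@arCoefficient,
                       config@bandHz, config@trSeconds)
    noise <- matrix(stats::rnorm(config@nTimepoints * nrow(subject@coords),
                                 sd = config@voxelNoiseSd),
                    config@nTimepoints, nrow(subject@coords))
    new("VoxelDataset",
      subjectId = subject@subjectId, sessionId = "ses2",
      groupLabel = subject@groupLabel, coords = subject@coords,
      series = L[, labels, drop = FALSE] + noise)
  })
}

#' Session coupling matrix actually used for a second session
#'
#' Exposes the perturbed coupling parameters that
#' [generateSessionPair()] draws for a subject, for calibration studies of
#' session-state variability.
#' @inheritParams generateSessionPair
#' @return the session-2 region coupling matrix.
#' @export
sessionCoupling <- function(config, subject) {
  C <- if (subject@groupLabel == "control") config@baseCoupling
       else patientCoupling(config)
  subjIndex <- as.integer(sub("^S", "", subject@subjectId))
  withSeed(deriveSeed(config@seed, 100000L + subjIndex), {
    if (config@sessionStateSd > 0) {
      R <- nrow(C)
      pert <- matrix(0, R, R)
      pert[upper.tri(pert)] <- stats::rnorm(R * (R - 1) / 2,
                                            sd = config@sessionStateSd)
      pert <- pert + t(pert)
      C <- projectToCorrelation(C + pert)
    }
    C
  })
}
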