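#' Assemble and validate a pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end run: the synthetic
#' cohort (or datasets supplied by the caller), whether to prewhiten, how to
#' define regions (a functional atlas built from the control subjects only,
#' or a reference label volume), graph construction, the registry, the
#' nested cross-validation, and the selection-frequency null.
#'
#' @param synthetic a [SyntheticConfig-class] (ignored when `datasets` is
#'   supplied to [runPipeline()]).
#' @param prewhiten logical, default TRUE.
#' @param atlasMode `"functional"` (default) or `"reference-label"`.
#' @param referenceAtlasPath NIfTI label volume, required for
#'   reference-label mode.
#' @param nRegions K for the functional atlas, default 8.
#' @param connectivity spatial adjacency rule, default 6.
#' @param density binarization density, default 0.30.
#' @param communitySeed seed for Louvain, default 1.
#' @param registry [measureRegistry()] configuration list.
#' @param nOuter,nInner,nPartitions,cvSeed cross-validation layout
#'   (defaults 5, 4, 10).
#' @param spec a [classifierSpec()].
#' @param screenThreshold default 0.60.
#' @param maxFeatures default 40.
#' @param alpha selection-null significance level, default 0.001.
#' @param outputDir run directory, default a fresh tempdir subdirectory.
#' @return validated configuration list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           prewhiten = TRUE,
                           atlasMode = c("functional", "reference-label"),
                           referenceAtlasPath = NULL,
                           nRegions = 8L, connectivity = 6L,
                           density = 0.30, communitySeed = 1L,
                           registry = list(),
                           nOuter = 5L, nInner = 4L, nPartitions = 10L,
                           cvSeed = 1L,
                           spec = classifierSpec(),
                           screenThreshold = 0.60, maxFeatures = 40L,
                           alpha = 0.001,
                           outputDir = tempfile("fcnetclass_run_")) {
  atlasMode <- match.arg(atlasMode)
  if (atlasMode == "reference-label" && is.null(referenceAtlasPath))
    stop("reference-label mode requires referenceAtlasPath")
  validObject(synthetic)
  stopifnot(density > 0, density <= 1, nRegions >= 2L)
  # desk-scale guardrail on the voxel-level distance matrix
  if (prod(synthetic@gridDims) > 12L^3)
    stop("synthetic grid above 12x12x12 voxels; downsample before parcellation")
  structure(list(synthetic = synthetic, prewhiten = prewhiten,
                 atlasMode = atlasMode,
                 referenceAtlasPath = referenceAtlasPath,
                 nRegions = as.integer(nRegions),
                 connectivity = connectivity, density = density,
                 communitySeed = as.integer(communitySeed),
                 registry = registry,
                 nOuter = as.integer(nOuter), nInner = as.integer(nInner),
                 nPartitions = as.integer(nPartitions),
                 cvSeed = as.integer(cvSeed), spec = spec,
                 screenThreshold = screenThreshold,
                 maxFeatures = as.integer(maxFeatures), alpha = alpha,
                 outputDir = outputDir),
            class = "PipelineConfig")
}

#' Run the end-to-end pipeline
#'
#' simulate (or accept datasets) -> prewhiten -> parcellate -> graphs and
#' features -> double cross-validation -> selection-frequency significance
#' -> report files. The functional atlas is always built from the control
#' subjects only. All stage outputs are persisted under the run directory
#' together with a JSON manifest recording seeds, stage settings and the md5
#' hash of every output file; re-running the same configuration reproduces
#' every output bit for bit.
#'
#' @param config a [pipelineConfig()].
#' @param datasets optional list of [VoxelDataset-class] to analyse instead
#'   of simulating.
#' @param verbose print stage progress, default TRUE.
#' @return the run directory path, invisibly; the loaded results are
#'   attached as attributes `results`, `significance`, `featureTable`,
#'   `atlas`.
#' @export
runPipeline <- function(config, datasets = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- config$outputDir
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %-12s %6.1fs", name, proc.time()[3] - t0)
    r
  }

  truth <- NULL
  if (is.null(datasets)) {
    sim <- stage("simulate", generateCohort(config$synthetic))
    datasets <- sim$datasets
    truth <- sim$truth
  }
  labels <- vapply(datasets, groupLabel, character(1))
  subjects <- vapply(datasets, subjectId, character(1))
  utils::write.csv(data.frame(subject_id = subjects, group = labels),
                   file.path(out, "subjects.csv"), row.names = FALSE)

  if (config$prewhiten)
    datasets <- stage("prewhiten", lapply(datasets, prewhitenDataset))

  atlas <- stage("parcellate", {
    if (config$atlasMode == "reference-label") {
      readAtlas(config$referenceAtlasPath)
    } else {
      controls <- datasets[labels == "control"]
      if (!length(controls)) stop("no control subjects for the atlas")
      grp <- concatenateGroup(controls)
      C <- correlationMatrix(grp@series)
      dend <- constrainedWard(correlationDistance(C), grp@coords,
                              config$connectivity)
      cutDendrogram(dend, config$nRegions)
    }
  })
  writeAtlas(atlas, file.path(out, "atlas.nii.gz"))

  ft <- stage("features", {
    graphs <- lapply(seq_along(datasets), function(s) {
      g <- weightedGraph(regionTimeSeries(datasets[[s]], atlas),
                         subjectId = subjects[s])
      g <- binarizeDensity(g, config$density)
      detectCommunities(g, config$communitySeed)
    })
    assembleFeatures(graphs, subjects, config$registry)
  })
  writeFeatureTable(ft, file.path(out, "features.csv"))

  res <- stage("classify", {
    plan <- makeCVPlan(subjects, labels, config$nOuter, config$nInner,
                       config$nPartitions, config$cvSeed)
    runDoubleCV(ft, labels, plan, config$spec, config$screenThreshold,
                config$maxFeatures)
  })
  utils::write.csv(res@curves, file.path(out, "curves.csv"),
                   row.names = FALSE)
  mr <- misclassificationRate(res)
  utils::write.csv(data.frame(subject_id = names(mr), group = labels,
                              misclassification_rate = unname(mr)),
                   file.path(out, "misclassification.csv"),
                   row.names = FALSE)
  traceDf <- do.call(rbind, lapply(res@traces, function(tr)
    data.frame(partition = tr$partition, fold = tr$fold,
               nScreened = length(tr$screened), bestStep = tr$bestStep,
               testAccuracy = tr$testAccuracyByStep[tr$bestStep],
               selected = paste(tr$sfsOrder, collapse = ";"))))
  utils::write.csv(traceDf, file.path(out, "traces.csv"), row.names = FALSE)

  sig <- stage("significance",
               significantFeatures(res, alpha = config$alpha))
  utils::write.csv(sig, file.path(out, "significant_features.csv"),
                   row.names = FALSE)

  summaryJson <- list(
    nSubjects = length(subjects),
    accuracy = res@summary$accuracy,
    sensitivity = res@summary$sensitivity,
    specificity = res@summary$specificity,
    null = attr(sig, "null"),
    seeds = list(synthetic = config$synthetic@seed, cv = config$cvSeed,
                 community = config$communitySeed))
  jsonlite::write_json(summaryJson, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  stage("report", makeReport(out))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "fcnetclass",
    version = as.character(utils::packageVersion("fcnetclass")),
    seeds = summaryJson$seeds,
    settings = list(prewhiten = config$prewhiten,
                    atlasMode = config$atlasMode,
                    nRegions = config$nRegions, density = config$density,
                    nOuter = config$nOuter, nInner = config$nInner,
                    nPartitions = config$nPartitions,
                    screenThreshold = config$screenThreshold,
                    maxFeatures = config$maxFeatures, alpha = config$alpha),
    hashes = as.list(tools::md5sum(files)))
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(out, results = res, significance = sig,
                      featureTable = ft, atlas = atlas, truth = truth))
}

#' Generate report files for a completed run
#'
#' Writes accuracy-versus-features curves (single and double CV), the
#' selection-frequency histogram with its expected-null overlay, and the
#' misclassification-rate distribution, as CSV tables plus PNG figures under
#' `<runDir>/report/`.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @return the report directory, invisibly.
#' @export
makeReport <- function(runDir) {
  need <- c("curves.csv", "significant_features.csv", "misclassification.csv",
            "summary.json")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("incomplete run: missing ", paste(missing, collapse = ", "))
  rep <- file.path(runDir, "report")
  dir.create(rep, showWarnings = FALSE)
  curves <- utils::read.csv(file.path(runDir, "curves.csv"))
  sig <- utils::read.csv(file.path(runDir, "significant_features.csv"))
  mr <- utils::read.csv(file.path(runDir, "misclassification.csv"))
  summaryJson <- jsonlite::read_json(file.path(runDir, "summary.json"))

  grDevices::png(file.path(rep, "accuracy_vs_features.png"), 700, 500)
  plot(curves$step, curves$singleCV, type = "b", pch = 16, col = "steelblue",
       ylim = range(c(curves$singleCV, curves$doubleCV, 0.4, 1), na.rm = TRUE),
       xlab = "number of selected features", ylab = "accuracy",
       main = "Single vs double cross-validation")
  graphics::lines(curves$step, curves$doubleCV, type = "b", pch = 17,
                  col = "firebrick")
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("bottomright", c("single CV (validation)",
                                    "double CV (test)"),
                   col = c("steelblue", "firebrick"), pch = c(16, 17))
  grDevices::dev.off()

  null <- summaryJson$null
  freqTab <- table(factor(sig$frequency, levels = 0:null$nFold))
  hist <- data.frame(frequency = as.integer(names(freqTab)),
                     observed = as.integer(freqTab))
  hist$expected <- expectedFrequencyCounts(null$F,
    frequencyNull(null$F, null$S, null$nFold, null$alpha))$expected
  utils::write.csv(hist, file.path(rep, "frequency_histogram.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(rep, "frequency_histogram.png"), 700, 500)
  graphics::barplot(hist$observed, names.arg = hist$frequency,
                    xlab = "selection frequency", ylab = "number of features",
                    main = "Observed vs expected selection frequencies")
  graphics::lines(seq_along(hist$frequency) * 1.2 - 0.5, hist$expected,
                  col = "firebrick", lwd = 2)
  grDevices::dev.off()

  grDevices::png(file.path(rep, "misclassification_rate.png"), 700, 500)
  graphics::hist(mr$misclassification_rate, breaks = seq(0, 1, by = 0.1),
                 xlab = "misclassification rate", main = "Per-subject MR")
  grDevices::dev.off()

  utils::write.csv(curves, file.path(rep, "accuracy_vs_features.csv"),
                   row.names = FALSE)
  invisible(rep)
}
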