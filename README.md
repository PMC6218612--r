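# fcnetclass

Data-driven discovery of network biomarkers from resting-state functional
time series, with the statistical safeguards that make such biomarkers
believable: spectral prewhitening against autocorrelation-inflated
correlations, and nested (double) cross-validation so that reported accuracy
never comes from subjects that informed feature selection.

The package is aimed at methods researchers in functional neuroimaging and
network neuroscience who want a fully testable reference implementation of
this pipeline — including a synthetic-cohort generator with planted group
differences, so every stage can be validated without any clinical data.

## The method

For each subject-session, voxel time series $x_i(t)$ (T time points,
default 177 at TR = 2 s) are **prewhitened** by flattening their DFT
magnitude spectrum,

$$x^W_i(t) = \mathcal{F}^{-1}\!\left[\, X_i(f) / |X_i(f)| \,\right],$$

so the power spectrum is flat and zero-lag correlations are no longer
inflated by within-series autocorrelation. A **functional atlas** is built
from control subjects only: their series are concatenated per voxel, the
voxel-pair Pearson correlation matrix $C$ is converted to the correlation
distance $D = 1 - C \in [0,2]$, and voxels are agglomerated by Ward's
minimum-variance linkage under a spatial constraint (only clusters
containing neighboring voxels may merge), yielding contiguous regions at any
dendrogram cut $K$.

Per subject, region-averaged series give a weighted graph (Pearson weights,
negatives zeroed), binarized by rank at an exact 30% connection density,
plus a Louvain community partition. A registry of node, pair and global
graph measures (degree, clustering, betweenness, shortest-path distance,
matching index, generalized topological overlap, modularity, ...) becomes
the feature set: $K+2$ features per node measure, $K(K-1)/2 + 2$ per pair
measure, with non-finite features excluded table-wide.

Classification uses linear SVMs (C = 1) inside a **double cross-validation**:
10 random partitions × 5 outer folds; within each outer training set a
4-fold inner rotation screens single features (keep accuracy > 60%) and
drives **sequential forward selection** up to 40 features; the held-out fold
is touched only by the final frozen model. Feature-set stability is scored
against an exact binomial null: a feature entering one random $S$-of-$F$
selection has probability $S/F$, so its frequency across $N_{fold}$ sets is
$\mathrm{Binomial}(N_{fold}, S/F)$, and `significantFeatures()` flags
frequencies with tail probability below α = 0.001. Per-subject
misclassification rates ($MR = M/N_{perm}$), effect sizes
($d'$), shuffled-label chance distributions, comparator selectors
(independent, Fisher-LDA, AdaBoost-SVM) and a train-on-session-1 /
test-on-session-2 design round out the toolkit.

See `vignettes/fcnetclass-methods.Rmd` for the full model account and every
convention choice.

## Worked example

A 30-subject synthetic cohort with one planted coupling deficit between true
regions 1 and 2 (controls r ≈ 0.5, patients r ≈ 0.2):

```r
library(fcnetclass)

cfg <- syntheticConfig(
  gridDims = c(5, 5, 4), nTrueRegions = 6, nTimepoints = 177,
  nControls = 15, nPatients = 15,
  basePairs      = data.frame(regionA = 1, regionB = 2, value = 0.5),
  plantedEffects = data.frame(regionA = 1, regionB = 2, delta = -0.3),
  seed = 7)
sim <- generateCohort(cfg)
sim$datasets[[1]]
#> VoxelDataset S001 / ses1 (control): 177 timepoints x 100 voxels

datasets <- lapply(sim$datasets, prewhitenDataset)
y <- vapply(datasets, groupLabel, character(1))
grp  <- concatenateGroup(datasets[y == "control"])
dend <- constrainedWard(
  correlationDistance(correlationMatrix(seriesMatrix(grp))),
  voxelCoords(grp))
atlas <- cutDendrogram(dend, 6)
atlas
#> VoxelAtlas: 6 regions over 100 voxels (region size 16-18)

subjects <- vapply(datasets, subjectId, character(1))
graphs <- lapply(seq_along(datasets), function(s)
  detectCommunities(binarizeDensity(
    weightedGraph(regionTimeSeries(datasets[[s]], atlas), subjects[s]),
    density = 0.30), seed = 1))
ft <- assembleFeatures(graphs, subjects)
ft
#> FeatureTable: 30 subjects x 169 features; 23 dropped as non-finite

plan <- makeCVPlan(subjects, y, nOuter = 5, nInner = 4, nPartitions = 4,
                   seed = 11)
res <- runDoubleCV(ft, y, plan, maxFeatures = 4)
res
#> RunResults: 20 fold traces; pooled accuracy 0.925, sensitivity 0.917,
#>   specificity 0.933

head(accuracyCurves(res), 4)
#>   step  singleCV  doubleCV
#> 1    1 0.9604167 0.9333333
#> 2    2 0.9875000 0.9083333
#> 3    3 0.9895833 0.8833333
#> 4    4 0.9875000 0.8750000

head(significantFeatures(res, alpha = 0.001), 3)
#>                featureId frequency       pValue significant
#> 1 correlationWeight_p3_5        16 4.655585e-10        TRUE
#> 2            strength_sd         8 8.799434e-03       FALSE
#> 3   correlationWeight_sd         7 3.037113e-02       FALSE
```

Reading the output: the inner-validation ("single CV") curve sits above the
held-out ("double CV") curve — the overfitting gap that makes double CV
necessary. The one feature flagged as selected more often than chance,
`correlationWeight_p3_5`, is the coupling weight between the two atlas
regions that recover the planted pair: the pipeline found the planted
biomarker and nothing else. Per-subject misclassification rates are
available via `misclassificationRate(res)`, chance levels via
`shuffledChance()`, and the whole chain can be run in one call with
`runPipeline(pipelineConfig(...))`, which persists every stage plus a
manifest under an output directory.

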