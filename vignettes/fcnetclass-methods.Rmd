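---
title: "Network-measure biomarker discovery with fcnetclass: models and methods"
author: "fcnetclass authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-measure biomarker discovery with fcnetclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Resting-state functional imaging produces, for each subject, tens of
thousands of voxel time series. A common route to a disease biomarker is to
summarise those series as a brain *network* — regions as nodes, correlations
as edges — extract graph-theoretic measures, and ask which measures separate
patients from controls under a classifier. Two methodological hazards
dominate this design: spurious cross-correlation induced by the strong
autocorrelation of BOLD-like signals, and optimistic accuracy estimates when
the same subjects inform both feature selection and the reported
performance. `fcnetclass` implements a pipeline that addresses both — by
spectral prewhitening of every series and by a nested (double)
cross-validation in which held-out test folds never touch selection — and
ships a synthetic-cohort generator so that every stage is testable without
access to any clinical data.

# Pipeline overview

1. **Simulation / input** — `generateCohort()` or user-provided
   `VoxelDataset` objects (NIfTI + CSV I/O via `writeDataset()` /
   `readDataset()`).
2. **Prewhitening** — `prewhitenSeries()`, `prewhitenDataset()`.
3. **Parcellation** — `concatenateGroup()`, `correlationMatrix()`,
   `correlationDistance()`, `constrainedWard()`, `cutDendrogram()`.
4. **Graphs and features** — `regionTimeSeries()`, `weightedGraph()`,
   `binarizeDensity()`, `detectCommunities()`, `measureRegistry()`,
   `assembleFeatures()`.
5. **Classification** — `makeCVPlan()`, `runDoubleCV()` (screen, sequential
   forward selection, held-out evaluation), comparators
   (`selectIndependent()`, `selectLDA()`, `adaboostClassify()`,
   `crossSessionEval()`).
6. **Selection-frequency statistics** — `significantFeatures()` against an
   exact binomial null.
7. **Orchestration** — `pipelineConfig()` + `runPipeline()` +
   `makeReport()`.

# Spectral prewhitening

For a series $x(t)$ of length $T$ with DFT $X(f)$, the prewhitened series is
the inverse DFT of $X(f)/|X(f)|$: every retained frequency carries unit
power, so the power spectrum is flat and the circular autocorrelation is an
impulse. The transform uses the series' own length as DFT length (no
padding, no taper); it is a-causal and circular by construction, which is
appropriate because only zero-lag similarity is consumed downstream.

Two numerical conventions matter:

* **Zero-magnitude bins.** Division by $|X(f)|$ is undefined where the
  spectrum vanishes. Bins whose magnitude does not exceed
  `zeroTol` ($10^{-12}$ relative to the maximum) are set to zero rather than
  normalised — no energy is invented at frequencies the data do not contain.
* **The DC bin is always zeroed.** The intended inputs are band-limited,
  mean-free series; removing DC reproduces that property and makes the
  downstream cosine similarity identical to the Pearson correlation. A
  consequence worth knowing: with DC removed, the circular autocorrelation
  at nonzero lags is not exactly zero but a uniform $-1/(T-1)$ — the
  mean-removal floor. The test suite asserts exactly this.

Prewhitening is idempotent (retained bins already have unit magnitude), and
is applied per voxel column, independently.

# Functional parcellation

The group atlas is built from **control subjects only** (disease is expected
to distort connectivity; the atlas should reflect the shared healthy
organisation), by concatenating their prewhitened series voxel-wise,
computing the voxel-by-voxel Pearson correlation matrix $C$, and clustering
the correlation distance $D = 1 - C \in [0, 2]$.

Clustering is agglomerative with **Ward's minimum-variance linkage under a
spatial constraint**: two clusters may merge only if they contain at least
one pair of spatially neighboring voxels, so every cluster at every level of
the dendrogram — hence every region of every cut — is spatially contiguous.

Design choices the literature leaves open, fixed here:

* **Neighborhood rule.** "Spatially neighboring" is face adjacency
  (6-connectivity) by default, the strictest standard notion; 18 and 26 are
  available via the `connectivity` argument.
* **Ward on a precomputed distance.** The supplied distances are squared and
  merged with the Lance–Williams recurrence; recorded heights are square
  roots of the criterion. With a fully connected adjacency this reproduces
  `hclust(method = "ward.D2")` exactly, which the tests verify against that
  independent implementation.
* **Ties** in the merge criterion are broken by the lexicographically
  smallest cluster-id pair, making the dendrogram deterministic.
* **Inversions.** Under a spatial constraint Ward heights need not be
  monotone; the merge history is recorded as-is and no monotonicity is
  asserted.
* **Memory guardrail.** The dense $N \times N$ matrix is only materialised
  below `maxVoxels` (default 5000) columns; full-brain voxel counts are out
  of desk scope and must be downsampled first.
* A **disconnected** voxel graph cannot produce a full merge tree and is
  rejected before clustering starts.

Cutting at $K$ regions replays the first $N - K$ merges; labels are
renumbered 1..K by smallest member voxel. `atlasOverlapReport()` describes
data-driven regions by the reference labels they overlap, percentage-wise.

# Subject graphs and the measure registry

Per subject, voxel series are averaged within regions (unweighted mean),
and the region-by-region Pearson correlation becomes the weighted adjacency.
**Negative weights are set to zero**: their physiological interpretation is
contested and they are empirically rare on coupled data; the zeroed fraction
is recorded on the graph (`negativeFraction`). Self-loops are excluded.

The binary graph keeps exactly $\lfloor d \cdot K(K-1)/2 \rfloor$ strongest
weights at target density $d$ (default 30%). Rank thresholding, rather than
solving for a scalar weight cutoff, realises the density *exactly* even with
tied weights; ties at the cut fall to the lexicographically first pairs.
Community structure is detected with Louvain modularity maximisation **on
the weighted graph** (binarization exists only to serve binary-specific
measures), with a fixed seed for determinism.

`measureRegistry()` computes a documented registry: ten node measures
(degree, strength, clustering, local efficiency, betweenness, eigenvector
centrality, closeness, k-coreness, participation coefficient, within-module
degree z-score), six pair measures (shortest-path distance, matching index,
generalized topological overlap, edge betweenness, raw neighborhood overlap,
correlation weight) and ten global measures. Conventions:

* **Matching index** defaults to the Jaccard form — common neighbors of the
  pair (excluding the pair itself) over the union of their neighbor sets —
  with the degree-sum ("bct") variant behind `matchingVariant`. Both agree
  at the 0 and 1 extremes and both are oracle-tested.
* **GTOM** uses $m = 2$ steps by default
  (`gtomSteps`), with the adjacency-corrected ratio
  $(|N_m(i) \cap N_m(j)| + a_{ij})/(\min(|N_m(i)|,|N_m(j)|) + 1 - a_{ij})$.
  Note the correction credits only direct edges: in a saturated graph
  adjacent pairs reach 1 while non-adjacent pairs top out at $(K-2)/K$.
* **Degenerate values** (distances between unreachable nodes, assortativity
  of regular graphs, closeness in disconnected graphs) stay non-finite and
  are handled by the exclusion rule below. Clustering of nodes with fewer
  than two neighbors is 0, the usual toolbox convention. Edge betweenness of
  a non-edge is 0.

`assembleFeatures()` lays measures out as one row per subject: each node
measure contributes $K + 2$ features (per node, plus mean and sd across
nodes), each pair measure $K(K-1)/2 + 2$, each global measure one. Mean and
sd aggregate **over finite values only**; any feature non-finite for at
least one subject is dropped for *all* subjects and recorded in the table's
`dropped` slot, so the retained matrix is entirely finite.

# Double cross-validation with sequential forward selection

`makeCVPlan()` draws, for each of `nPartitions` (default 10) random
partitions, `nOuter` (default 5) equal-sized outer folds; each fold serves
once as the held-out test set, so each subject is tested `nPartitions`
times. Within an outer training set, `nInner` (default 4) inner folds rotate
as the validation set — the "shuffled four times" scheme is read as a 4-fold
rotation, so that every non-test subject validates exactly once. Partitions
whose outer fold would lack a class are re-drawn with a warning; inner
rotations whose training part would lack a class are re-drawn quietly.

Per (partition, fold) unit:

1. **Standardisation.** Features are z-scored with non-test-subject
   statistics. Margin classifiers are scale-sensitive, and using any
   test-fold statistic would leak; the same transform is frozen and applied
   to the test fold.
2. **Screen.** Each feature alone trains a linear SVM (C = 1 by default,
   `classifierSpec()`) across the inner rotation; only features with mean
   validation accuracy **strictly above** the 60% threshold survive.
3. **SFS.** Starting from the best single feature (screen accuracies are
   reused as step-1 accuracies — same folds, same definition), greedily add
   the candidate maximising mean inner-validation accuracy of the combined
   set, up to `maxFeatures` (default 40). Ties fall to catalog order.
4. **Evaluation.** For every selection prefix, an SVM trained on all
   non-test subjects is applied to the test fold; accuracy
   $(TP+TN)/T$, sensitivity $TP/P$ and specificity $TN/N$ are recorded with
   patients as the positive class.

The inner-validation curve is the *single-CV* performance; the held-out
curve is the *double-CV* performance. For per-subject misclassification
counting, each unit predicts at its **best step** — the prefix length
maximising mean inner accuracy, earliest on ties; the misclassification rate
is then $MR = M/\texttt{nPartitions}$. Chance level comes from re-running
the whole machinery on shuffled labels (`shuffledChance()`). Effect sizes
use $d' = (\bar{x}_{patient} - \bar{x}_{control}) / \sqrt{(s^2_{patient} +
s^2_{control})/2}$ — patient minus control by convention — with a two-sample
t-test p-value.

Comparators mirror common alternatives: top-$k$ by single-feature accuracy
(`selectIndependent()`), Fisher-LDA ranking with a Moore–Penrose
pseudo-inverted within-class scatter (`selectLDA()`, always defined even
with more features than subjects), AdaBoost over ten linear-SVM weak
learners trained on weight-proportional resamples (`adaboostClassify()`;
degenerate rounds are skipped with a warning, weights re-normalise to one
every round), and a cross-session design (`crossSessionEval()`) that
freezes selection and model on session 1 and scores session 2.

# The selection-frequency null

Across all units the pipeline produces `nPartitions × nOuter` selected sets
(50 under the defaults). Under the null that each set of size $S$ is drawn
uniformly from the $F$ screened candidates, a designated feature enters one
set with hypergeometric probability $S/F$, and its total frequency across
$N_{fold}$ independent sets is $\mathrm{Binomial}(N_{fold},\, S/F)$.
`frequencyPvalue()` returns the exact upper tail; `significantFeatures()`
tallies frequencies, uses the **mean screened count** over units as the
single representative $F$ (the screen output varies by fold), and flags
features below `alpha` (default 0.001 — a formalisation of "appearing this
often by chance is very small"). Treating the sets as independent despite
fold overlap is an approximation inherited from the design this pipeline
follows; the Monte-Carlo comparison in the test suite quantifies its
accuracy for the modelled two-stage draw. With the reference configuration
$F = 1618$, $S = 40$, $N_{fold} = 50$, the α = 0.001 cutoff falls at or
below a frequency of ten.

# What the synthetic generator emulates — and what it does not

`generateCohort()` produces cohorts matching the statistical structure the
pipeline assumes:

* a 3D voxel grid partitioned into contiguous true regions, grown
  breadth-first from random seeds under the same 6-connectivity the
  parcellation uses;
* per region a latent AR(1) signal — default lag-1 autocorrelation 0.4,
  typical of band-limited BOLD at a 2 s sampling interval — with unit
  stationary variance; signals are coupled across regions through the
  symmetric square root of a coupling correlation matrix, so the target
  correlations hold in expectation and each column stays AR(1);
* 177 time points at TR = 2 s by default, matching a ~6-minute resting
  scan;
* patients differ from controls only through `plantedEffects`: additive
  deltas on designated coupling entries. Deltas that break positive
  semidefiniteness are **rejected with the offending pair named**, never
  silently projected — projection would distort the planted effect size;
* independent Gaussian voxel noise (sd 1 by default, i.e. noise on the
  order of the signal);
* paired sessions: `generateSessionPair()` re-draws the latent signals and
  perturbs the coupling matrix with symmetric noise of sd `sessionStateSd`
  (then projects back to a valid correlation matrix) — a knob for
  session-specific brain state. No empirical estimate of that variability
  is available, so the knob is free, not calibrated.
* optional band-limiting of the latent signals (`bandHz`) is off by
  default: the AR coefficient is the primary autocorrelation control, and
  the pipeline's properties are tested against autocorrelation, not a
  specific band.

It deliberately does **not** model scanner physics, motion, physiological
confounds, hemodynamic convolution, spatial smoothing or any preprocessing
chain — generation starts at the "preprocessed voxel time series" level.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
statistical correctness (no leakage, calibrated nulls, recovery of planted
effects), not robustness to real acquisition artifacts.

# Problem sizes and numerical choices

The examples and tests run at desk scale by the package's own choice:
grids up to $6 \times 6 \times 6$ voxels (the pipeline guardrail refuses
functional parcellation above $12^3$), 8–12 atlas regions, cohorts of tens
to a hundred subjects, selection budgets of 5–40 features. The end-to-end
recovery scenario plants a single coupling deficit sized to a region-level
effect of about $|d'| = 2$ (delta −0.15 on a baseline coupling of 0.45 at
$T = 177$) and extracts features at a parcellation finer than the true
region count, so that the screened candidate pool is comfortably larger
than the selection set — the regime in which the selection-frequency null
is informative. Region-level effects detectable in this regime are large by
clinical standards; the package measures method validity, not clinical
attainability.

Other numerical conventions: coupling matrices are validated positive
semidefinite with an $10^{-8}$ eigenvalue tolerance; correlation entries are
clipped to $[-1, 1]$ against floating-point drift; correlation projection
after session perturbation clips eigenvalues and renormalises the diagonal;
all randomness flows from explicit seeds through a single derivation
function, so every advertised output is bit-reproducible.

# Known limitations

* The registry is a documented stand-in for a longer historical measure
  list; measures are included when a standard definition and an independent
  oracle exist.
* The constrained Ward implementation is dense ($O(N^2)$ memory,
  $O(N^3)$ vectorised work) — appropriate for downsampled desk-scale
  grids, not whole-brain voxel counts.
* The selection-frequency null ignores fold overlap (inherited
  approximation, quantified by simulation in the tests).
* Cross-session variability is a free parameter of the generator; absent an
  empirical calibration target, analyses of it are qualitative
  (more state noise, less cross-session generalisation).
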