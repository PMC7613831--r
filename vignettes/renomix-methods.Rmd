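---
title: "Methods and design of renomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of renomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`renomix` packages the analysis chain by which a combined dietary-plus-
pharmacological intervention (DMT) is linked, in two rat models of diabetic
kidney disease, to PPARα-driven fatty-acid oxidation (FAO) in the proximal
tubule. This vignette documents the statistical models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the procedure left
room for choice.

## Differential expression

The expression engine is a deliberately transparent two-group
negative-binomial (NB) Wald test rather than a full shrinkage pipeline.

**Normalization.** `estimateSizeFactors()` implements median-of-ratios:
per sample, the median over genes (restricted to genes whose geometric mean
across samples is positive) of the count divided by that geometric mean.
It agrees with the reference implementation in the DESeq2 package to within
the tie-handling of an even-sized median (cross-checked in the tests).

**Dispersion.** `estimateDispersions()` is the method-of-moments estimator
on normalized counts: the within-group variance pooled across groups gives
`alpha = max(1e-8, (s² − μ̄)/μ̄²)` per gene, floored so constant genes stay
defined. At the study's sample sizes (n = 6–9 per group) the per-gene
estimate is noisy; plugged directly into a normal-reference Wald statistic
it inflates the type-I error to roughly 8% at a nominal 5%. `waldTest()`
therefore moderates: its default (`moderation = "common"`) replaces each
per-gene value with the across-gene mean before it enters the standard
error. This is a light analogue of the empirical-Bayes shrinkage that
mature tools apply and is exact for the synthetic model, which draws all
genes at one shared dispersion; `moderation = "none"` restores the raw
per-gene behaviour. The calibration (empirical type-I error within
0.05 ± 0.01 on a 2,000-gene, 6 + 6 null study) is asserted in the test
suite.

**Test.** The log2 fold-change is the log ratio of group means of
normalized counts; its standard error comes from the NB variance
`μ + αμ²` by the delta method; `z = log2FC/SE` is referred to the standard
normal, two-sided, and BH-adjusted (`adjustBH()` wraps the step-up rule;
an independent brute-force oracle re-derives it in the tests). Genes with
all-zero counts are flagged and assigned p = 1 and log2FC = 0 rather than
dropped, keeping the gene universe identical across contrasts. When
exactly one group mean is zero a pseudo-mean of 0.5 keeps the estimate
finite.

**Calling and concordance.** `callDEGs()` applies the study gates — the
fold-change boundary is *inclusive* (|FC| ≥ 1.3) and the adjusted-p gate
*strict* (padj < 0.05), mirroring the printed inequalities.
`concordantDEGs()` intersects two DEG sets requiring equal direction;
`correctedFraction()` counts disease DEGs (SHAM vs healthy) that reappear
in the treatment contrast (DMT vs SHAM) with *opposite* direction. The
direction requirement is the package's reading of "corrected"; a
`mode = "any"` switch drops it. Percentages round half away from zero to
one decimal (`roundHalfUp()`), matching how the printed values
(54.4%, 26.0%, 75.8%, 65.3%) arise from their counts.

**Transform and PCA.** The regularized-log transform of the upstream
tooling is approximated by `log2(k/s + 1)`: the downstream uses (PCA,
per-animal correlation) only need a monotone variance-stabilizing
transform, and the exact regularization is internal to the original
package. `pcaScores()` is plain SVD of the column-centered matrix with a
deterministic sign convention (largest-magnitude loading positive).

## Enrichment and regulator scoring

`oraTest()` is the hypergeometric upper tail P(X ≥ k) with BH adjustment
across sets. The universe defaults to the union of the collection, but the
recommended (and pipeline-used) choice is all genes tested for
differential expression — the standard guard against background inflation.
The commercial upstream-regulator score is proprietary, so
`regulatorActivation()` uses the documented signed consistency score
`z = (n_consistent − n_inconsistent)/√n` over a regulator's DEG-overlapping
targets, preserving the qualitative contract (activated at z ≥ 2,
inhibited at z ≤ −2); it is labelled as such and should not be read as a
reimplementation of the proprietary statistic.

## Cell-type localization and stratification

Transcripts are assigned to one of the 14 tubular epithelial cell types
(fixed ontology S1, S2, S3, DTL1–3, ATL, mTAL, cTAL, DCT, CNT, CCD, OMCD,
IMCD) by **argmax abundance** in the atlas. The original analysis read
localization off heatmap dendrograms; that criterion is visual and not
reproducible, whereas "site of maximal abundance" is the stated quantity
and deterministic. Ties take the first cell type in ontology order and are
flagged. Features absent from the atlas are counted in an explicit
"absent" stratum, never dropped. Whether raw or per-feature-normalized
abundances should feed the argmax is unstated in the source; raw values
are used (argmax is invariant to per-feature scaling, so this matters only
for cross-feature summaries). `stratifyByResponsiveness()` nests
responsiveness (≥ 1 entity of a class; focal-entity share), atlas
presence, and proximal-tubule (S1–S3) versus rest-of-tubule compartment,
with child counts summing to their parents — an invariant the tests check
on random inputs.

## ¹H-NMR spectral processing

**Baseline.** `baselineCorrect()` estimates a running low quantile:
windows of 1000 points anchored every 500 points, quantile 0.1 (the cited
parameter set; units are axis points). Two refinements make the estimate
usable quantitatively: the quantile value is assigned to its *expected
position inside the window* (making the estimate exact on locally linear
backgrounds) and, because the running q-quantile of baseline-plus-noise
sits `qnorm(q)` noise-SDs below the true baseline, the estimate is
recentered using a robust first-difference noise scale (exactly zero for
noiseless input, so the construction examples are unaffected).

**Peak detection.** `detectPeaksCWT()` convolves each spectrum with
unit-norm Ricker (Mexican-hat) kernels over a log-spaced scale ladder
(default 2–32 points), links local coefficient maxima into ridges from the
largest scale down (match tolerance of one scale, gap tolerance 2), and
keeps ridges spanning at least a third of the ladder whose peak
coefficient exceeds `minSNR` times a robust noise level (1.4826 × median
absolute smallest-scale coefficient, floored at 10⁻⁶ of the maximal
coefficient so numerically silent spectra cannot promote round-off to
peaks). Apex intensities are refined by a three-point parabola to remove
the sampling-grid bias. No installed package provides wavelet peak
picking, so this component is implemented here and exercised against
constructed spectra (isolated Gaussians, resolved pairs, pure noise).

**Grouping and the silhouette gate.** `groupPeaks()` single-links peak
positions and cuts at the tolerance (default 0.005 ppm — a configuration
value, not a claim about the original workflow, which does not state its
tolerance). If a sample contributes several peaks to one group only its
most intense is retained; the rest return to an unassigned pool.
`silhouetteFilter()` computes one-dimensional silhouettes
`s = (b − a)/max(a, b)` on member positions (cross-checked against
`cluster::silhouette`), dissolves groups whose mean silhouette falls below
0.6, regroups the dissolved members at a tolerance shrunk by 0.6 per
iteration (guaranteeing progress towards singletons), and repeats until
every retained group passes or 20 iterations elapse, at which point
still-failing groups are dropped with a warning. Two conventions the
source leaves open: singleton groups score 1 (so rare peaks are not
penalized), and a *lone* multi-member group — for which no between-cluster
distance exists — is dissolved only when its largest internal gap exceeds
the grouping tolerance.

**Filling and PQN.** Missing matrix entries are filled with the maximal
baseline-corrected intensity within ±0.005 ppm of the group position,
floored at zero. `pqnNormalize()` divides each sample by the median of its
entrywise quotients against the column-median reference spectrum
(zero-reference columns excluded); the median quotient is the dilution
estimate. The reference choice (median spectrum rather than a QC pool) is
exposed through the `reference` argument. Groups detected in fewer than
25% of samples are discarded before filling (`minGroupFraction`): sporadic
noise detections otherwise contribute quotient columns centred on 1
regardless of dilution and bias the median.

## Repeated double cross-validation classification

`fitRDCV()` follows the repeated double cross-validation scheme with
recursive variable elimination: per repetition, a stratified split into
`nOuter = 5` outer segments; per held-out segment, `nOuter − 1` inner
folds drive the elimination (train a forest, rank by mean decrease in
Gini, retain `ceiling(varRatio × current)` variables — with a guaranteed
decrease of at least one so the ladder always terminates at the floor of
2 — recording the inner validation misclassification rate at each count).
The averaged inner curve selects the count per flavor: `min` is the
smallest count attaining the minimal error; `max` is the largest count
whose error stays within `minErr + 0.05 × (maxErr − minErr)` — a
deterministic reading of "without compromising performance", exposed as
`maxTolerance`; `mid` is the rounded geometric mean. The forest is refit
at the selected count on the outer-training samples (variables ranked by
the inner-fold-averaged importance) and predicts the held-out segment;
held-out probabilities are averaged over repetitions and classified once
at the 50% threshold. Forests are standard bootstrap-aggregated CART
ensembles with the Gini criterion and √p variables per split (the
`randomForest` package; 500 trees by default), which is what the
mean-decrease-in-Gini importance presupposes. Reported importance is the
refit-forest importance averaged over repetitions, with never-selected
variables at zero. `aucScore()` is the Mann–Whitney rank statistic with
ties at one half, verified against an all-pairs oracle and the pROC
package.

## Morphometric endpoints

Closed forms with their constants: Weibel–Gomez `V = (β/d)·A^{3/2}` with
β = 1.38 (spheres) and d = 1.01 — these constants come from the cited
stereological method, are not printed in the study, and are exposed as
arguments; PFPD = 8000/PFPF nm over the fixed 8 µm GBM window; roundness
`4A/(πL²)`, which equals the inverse aspect ratio exactly on ellipses (a
property test draws random ellipses); Δ% = 100·(post − pre)/pre per
animal (summaries are the caller's choice); ΔΔCt with the healthy group as
calibrator, whose RQ geometric mean is 1 by construction.

## Correlation networks and molecular morphometrics

`pearsonMatrix()` correlates per-animal structure, transcript and
metabolite features (constant columns are dropped with a warning — they
have no defined correlation). `thresholdNetwork()` keeps |r| ≥ 0.5,
boundary inclusive, since the original filter removes strictly below 0.5.
`mdsCluster()` embeds `d = 1 − r` by classical (Torgerson) MDS in two
dimensions and cuts a complete-linkage tree of the embedding at
`kClusters`. The signed distance (rather than `1 − |r|`) is deliberate:
anti-correlated features should separate, preserving the sign structure of
the network. The cluster count is a configuration parameter (default 2:
a treatment-tracking and a disease-tracking community); the source does
not state one.

## The synthetic-data generator

The generator produces every input with recorded truth, under defaults
that constitute the package's reference study conditions:

- **Counts.** Two cohorts (ZDF, ZDSD) of healthy/SHAM/DMT with 6 samples
  per group, 2,000 genes, NB counts at shared dispersion 0.05, log-uniform
  library sizes in [0.7, 1.4] and base means in [20, 2000]. A 120-gene FAO
  module is disease-suppressed (−0.7 log2, SHAM vs healthy) and
  treatment-induced (+1.5 log2, DMT vs SHAM); a 120-gene fibrosis module
  is disease-induced (+1.5 log2) and fully reversed by treatment. The
  effect sizes are configuration values chosen for clear signal at n = 6,
  not claims about the deposited data; the shared dispersion matches the
  analysis model so parameter recovery is a fair test.
- **Atlas.** 80% of genes present; the maximal cell type of every feature
  is forced by construction (planted column = next-highest × a 2–6-fold
  enrichment), so truth is exact; 75% of FAO genes get a proximal-tubule
  argmax versus the 3/14 background rate.
- **Drug networks.** Target sets sized in the hundreds with
  fenofibrate/PPARα dominance over the FAO module (75% / 62% module
  coverage versus ≤ 12% for the other entities), an optional shared core,
  and an exactly honoured fenofibrate∩PPARα overlap when module planting
  is disabled. Planted shares are recorded over the union of both planted
  modules, which is the population the downstream stratification
  estimates.
- **NMR.** 36 spectra (healthy 11, untreated-mild 11, untreated-severe 8,
  DMT 6) on a 12,000-point 10→0.2 ppm axis: Gaussian peaks (Lorentzian
  optional) for clearance metabolites (down in disease), TCA intermediates
  (up in disease), nicotinamide-pathway metabolites (up after DMT), a
  dominant glucose cluster in untreated disease, and a dense stable
  background of ~60 peaks — real urinary peak matrices carry on the order
  of a hundred resolved groups, and the stable majority is what anchors
  the PQN median on dilution. Per-sample dilution is uniform on [0.5, 2];
  the smooth baseline (largest in untreated disease, emulating glucose
  interference) is *not* scaled by dilution, so quotient factors are
  identifiable; white noise at SD 0.01 of unit peak scale.
- **Morphometry.** Group-shifted normals truncated at zero for glomerular
  area, PFPF, GBM thickness and mitochondrial axes; minor axis and area
  are derived from the planted major axis and roundness so the roundness
  identity holds exactly on generated tables. The mitochondrial-shape
  feature entering the correlation network is planted to *track treatment
  response positively* (disease-depressed, DMT-restored): with the signed
  distance d = 1 − r, features must co-vary positively to co-cluster, so
  the generator encodes the qualitative claim — FAO transcripts, urinary
  nicotinamide metabolites and mitochondrial shape moving together under
  treatment — with one consistent sign convention. Real pars-recta
  roundness moves opposite in sign; the synthetic feature is a shape
  index, not a calibrated reproduction of it.

What the generator does **not** emulate: batch effects across library
chemistries, gene–gene correlation, overdispersion heterogeneity across
genes, peak-shape distortions (phasing, shoulders, J-coupling multiplets
beyond isolated lines), metabolite annotation, or inter-animal coupling
between omics layers beyond shared group structure. Passing tests
therefore demonstrate the correctness and calibration of the chain on its
stated model, not performance on raw deposited data.

## Problem sizes and determinism

Every generator and the whole rdCV fit are deterministic given a seed; the
pipeline manifest records parameters and output checksums so a run can be
reproduced exactly. The test suite and acceptance script use the reference
conditions directly where cheap (2,000-gene null and power studies, the
36-spectrum cohort) and scaled-down settings where the full defaults add
nothing but time: rdCV benchmarks run at nRep = 20 with 60-tree forests
(the selection behaviour stabilizes well before the default nRep = 100),
and the orchestrated pipeline's classifier stage defaults to nRep = 5 as a
demonstration. These sizes are the package's choices for its reference
checks; all algorithmic defaults remain the study's values.

## Known limitations

- The Wald engine omits independent filtering, outlier handling
  (Cook's distance), LFC shrinkage and multi-factor designs; it is a
  two-group engine by scope.
- The regulator score is a documented simplification, not the proprietary
  statistic it stands beside.
- Argmax localization ignores secondary expression sites that a dendrogram
  reading might capture.
- PQN assumes the majority of peak columns are dilution-stable; cohorts in
  which most of the metabolome shifts violate its premise (the generator's
  stable background encodes that assumption explicitly).
- Classical MDS of 1 − r is not guaranteed Euclidean; negative eigenvalues
  are truncated, which is the standard Torgerson behaviour.
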