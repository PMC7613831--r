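# renomix

Multi-omic analysis of renoprotective fatty-acid-oxidation (FAO) responses
in rat models of diabetic kidney disease (DKD).

## The scientific problem

In the ZDF and ZDSD rat models of DKD, an intervention combining dietary
restriction with five medications (fenofibrate, liraglutide, metformin,
ramipril, rosuvastatin — "DMT") protects the kidney. The analytical question
is *why*: which transcripts change concordantly in both models, which
nephron compartment they act in, which medication and which PPAR isotype
they respond to, and how those molecular changes relate to urinary
metabolites and tissue ultrastructure. `renomix` implements that analysis
chain as reusable, tested components:

- **Differential expression** — median-of-ratios size factors
  (s_j = median_i k_ij / (∏_j k_ij)^(1/n)), a per-gene two-group
  negative-binomial model with moment dispersion (Var = μ + αμ²), Wald
  z = log2FC / SE with BH-adjusted p, DEGs at |FC| ≥ 1.3 and padj < 0.05,
  cross-model concordance, and corrected-transcript fractions
  (disease DEGs reversed by treatment).
- **Enrichment** — hypergeometric over-representation P(X ≥ k) against
  gene-set collections, and a signed upstream-regulator activation score
  z = (n_consistent − n_inconsistent)/√n with calls at |z| ≥ 2.
- **Cell-type localization** — assignment of transcripts to the 14 tubular
  epithelial cell types (S1…IMCD) by site of maximal atlas abundance, with
  proximal-tubule (S1–S3) compartment calls and nested
  medication/PPAR-responsiveness stratification.
- **¹H-NMR spectral processing** — running-quantile baseline correction
  (window 1000, quantile 0.1, step 500), Mexican-hat continuous-wavelet
  peak detection with ridge linking, cross-sample peak grouping gated by a
  silhouette ≥ 0.6 iteration, peak filling, and probabilistic quotient
  normalization (PQN) whose median quotient estimates each sample's urinary
  dilution.
- **Classification** — repeated double cross-validation random forests
  (nOuter = 5, nRep = 100, varRatio = 0.85) with recursive elimination of
  the least informative variables, mean-decrease-in-Gini ranking,
  misclassifications at the 50% probability threshold, and rank-statistic
  AUC.
- **Morphometry** — Weibel–Gomez glomerular volume V = (β/d)·A^{3/2},
  podocyte foot-process diameter PFPD = 8000/PFPF nm, mitochondrial
  roundness 4A/(πL²), Δ% change, and ΔΔCt relative quantification.
- **Molecular morphometrics** — per-animal Pearson correlation of
  structure, transcript and metabolite features, a network thresholded at
  |r| ≥ 0.5, and clustering on a classical MDS embedding of d = 1 − r.

A synthetic-data generator plants known truth in every input — FAO and
fibrosis gene modules, proximal-tubule atlas enrichment,
fenofibrate/PPARα-dominant target networks, clearance / TCA / nicotinamide
metabolite families with per-sample dilution, and group-shifted
morphometry — so every stage is testable without any download.

## Worked example

```r
library(renomix)

cfg   <- syntheticStudyConfig(seed = 101)       # the reference conditions
zdf   <- simulateCountStudy(cfg, "ZDF")
zdsd  <- simulateCountStudy(cfg, "ZDSD")

degsZdf  <- callDEGs(waldTest(zdf,  c("DMT", "SHAM")))
degsZdsd <- callDEGs(waldTest(zdsd, c("DMT", "SHAM")))
conc <- concordantDEGs(degsZdf, degsZdsd)
conc
#> DEGSet: 240 genes ( 120 up / 120 down )
#>   contrast: DMT vs SHAM & DMT vs SHAM
#>   gates: |FC| >= 1.3 , padj < 0.05

net <- simulateDrugNetworks(cfg)
atl <- simulateAtlas(cfg)
strat <- stratifyByResponsiveness(conc, net, atl$atlas, "fenofibrate",
                                  c("fenofibrate", "liraglutide",
                                    "metformin", "ramipril", "rosuvastatin"))
strat
#> StratificationSummary (focal: fenofibrate )
#>   concordant DEGs: 240
#>   responsive to >=1 entity: 142 (59.2%)
#>   focal-responsive: 111 (78.2% of responsive)
#>   focal in atlas: 91 ; PT share 72.5%
```

The 240 concordant genes are the two planted 120-gene modules (recall is
100% with < 1% false positives at these sample sizes); 78.2% of the
drug-responsive ones respond to fenofibrate and 72.5% of those present in
the atlas localize to the proximal tubule — both within a fraction of a
percentage point of the generator's recorded truth.

The spectral chain, run on the simulated urinary cohort:

```r
sp  <- simulateNMRCohort(cfg)
out <- processSpectra(sp)           # baseline -> CWT -> group -> silhouette
                                    # -> fill -> PQN
nrow(out$groupTable$groups)         # 81 peak groups, all silhouettes >= 0.6
max(abs(out$factors / plantedTruth(sp)$dilution /
        mean(out$factors / plantedTruth(sp)$dilution) - 1))
#> ~0.014   (dilution factors recovered within ~1.4%)
```

`runPipeline(pipelineConfig(seed = 101))` chains all eight stages
(simulate → de → enrich → deconv → nmr → classify → measures → correlate)
and writes per-stage tables plus a manifest with parameter and checksum
records.

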