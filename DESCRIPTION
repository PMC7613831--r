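Package: renomix
Title: Multi-Omic Analysis of Renoprotective Fatty-Acid-Oxidation Responses
    in Rat Models of Diabetic Kidney Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the molecular basis of renoprotection by
    combined dietary restriction and pharmacotherapy in rat models of
    diabetic kidney disease. Implements negative-binomial Wald differential
    expression with cross-model concordance and corrected-transcript
    fractions, hypergeometric over-representation and upstream-regulator
    activation scoring, tubule cell-type localization of transcripts by
    maximal atlas abundance, drug-target network stratification, a full
    1D 1H-NMR spectral processing chain (running-quantile baseline
    correction, Mexican-hat continuous-wavelet peak detection,
    silhouette-gated peak grouping, peak filling, probabilistic quotient
    normalization), repeated double cross-validation random-forest
    classification with recursive variable elimination, closed-form
    morphometric endpoints (Weibel-Gomez glomerular volume, podocyte
    foot-process metrics, mitochondrial roundness, delta-percent, ddCt),
    and structure-transcript-metabolite correlation networks clustered by
    multidimensional scaling. A synthetic-data generator with recorded
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    pROC,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
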