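Package: qpcrStab
Title: Reference-Gene Stability Ranking and Validation for RT-qPCR
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting and validating reference genes for RT-qPCR
    normalization. Candidate genes are screened from an RNA-seq expression
    (TPM) matrix by expression level, coefficient of variation and
    between-tissue fold change; their threshold-cycle (Ct) profiles are then
    scored with four stability estimators (comparative delta-Ct, geNorm
    M-values with pairwise-variation V(n/n+1), a NormFinder-style variance
    decomposition, and the BestKeeper index) and aggregated into a consensus
    ranking by the geometric mean of rank positions. The geNorm pairwise
    variation determines how many reference genes are needed, and chosen
    normalizers are validated on a target gene with efficiency-aware
    2^-ddCt relative quantification. A synthetic-data generator reproduces
    the multi-tissue, multi-condition qPCR study design with known ground
    truth so every stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, Normalization, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CtExperiment.R'
    'results-methods.R'
    'bestkeeper.R'
    'consensus.R'
    'deltact.R'
    'genorm.R'
    'ddct.R'
    'descriptives.R'
    'io.R'
    'normfinder.R'
    'screen.R'
    'pipeline.R'
    'qpcrStab-package.R'
    'simulate.R'
    'utils.R'
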