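Package: acclimkit
Title: Thermal Dose, Dose-Response and Expression Analysis of Coral
    Acclimatization Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying durable thermal acclimatization in reef
    corals from short-term pre-exposure experiments. Converts temperature
    logger series into experimental Degree Heating Weeks (eDHW), fits
    Weibull dose-response curves of photosynthetic efficiency (fv/fm)
    against accumulated thermal dose to estimate ED10 bleaching thresholds,
    computes per-genotype acclimatization potential with a bootstrap
    broad-sense heritability estimator, screens gene expression for
    treatment responses and plasticity-correlated contigs, and performs
    rank-based (Mann-Whitney U) functional enrichment on continuous
    per-gene scores. Includes a synthetic-study generator with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Regression, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dose-response.R'
    'acclimatization.R'
    'acclimkit-package.R'
    'thermal-exposure.R'
    'expression.R'
    'enrichment.R'
    'synthetic-data.R'
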