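Package: miRcq
Title: Quality Control, Relative Quantification and Differential
    Expression for miRNA qPCR Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of TaqMan-style miRNA qPCR array data from
    biofluid extracellular vesicles: well-level quality filtering
    (detection-ceiling imputation, amplification-score and Cq-confidence
    exclusion, no-template-control contamination screening, detection-rate
    filtering), endogenous-control delta-delta-Cq relative quantification,
    Welch differential expression with Benjamini-Hochberg false discovery
    control and fold-change calling, sex-stratified two-way factorial ANOVA
    with Tukey post hoc comparisons, presence/absence profiling of
    size-exclusion chromatography fraction pools, miRNA target-prediction
    set-ensemble benchmarking against validated interactions, hypergeometric
    pathway over-representation, and a synthetic-data generator that emulates
    a balanced disease-by-sex-by-genotype cohort design for testing every
    stage without access to the original instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, fgsea, yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
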