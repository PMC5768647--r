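Package: firthseq
Title: Firth Logistic Differential Expression and Cross-Disease Rank
    Aggregation for Case/Control RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-alignment analysis of case/control bulk mRNA-Seq cohorts
    built around Firth penalized logistic regression of disease status on
    standardized normalized gene counts. Provides biotype and low-count
    filtering, median-of-ratios normalization, robust per-condition outlier
    winsorization, per-gene Firth differential expression with penalized
    likelihood-ratio tests and Benjamini-Hochberg correction, preranked
    gene-set enrichment with a gene-sampling permutation null, robust rank
    aggregation of gene lists via binomial order statistics, hypergeometric
    enrichment of differential-expression list partitions, and a
    negative-binomial cohort simulator with planted ground truth for
    end-to-end validation. Includes a pipeline orchestrator and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'gmt.R'
    'gsea.R'
    'compare.R'
    'firth.R'
    'de.R'
    'pipeline.R'
    'preprocess.R'
    'rra.R'
    'simulate.R'
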