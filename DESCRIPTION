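Package: transmrs
Title: Trans-Tissue Methylation Risk Scores for Case-Control Phenotypes
Version: 0.1.0
Authors@R:
    person("Open", "Methylomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for trans-tissue methylation risk score
    (MRS) analysis of case-control phenotypes from Illumina-style methylation
    arrays. Starting from normalized beta-value matrices of two tissues, the
    package performs sample and probe quality control, reference-based
    cell-type deconvolution, slide-associated principal component and
    surrogate-variable covariate construction, a mass-univariate discovery
    EWAS on M-values, co-methylation pruning of correlated CpGs within 2 kb,
    effect-weighted p-value-thresholded score construction, and
    covariate-adjusted logistic association with incremental Nagelkerke
    pseudo-R2 in the target tissue, including GWAS-locus include/exclude
    subsets and confounder-derived score controls. A synthetic-data module
    generates paired two-tissue datasets with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
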