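Package: phenocurate
Title: Curation and Quality Validation of Historical Genebank Regeneration Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating historical phenotypic records collected during
    seed regeneration of genebank accessions, where the accession-by-year
    incidence is strongly non-orthogonal. Implements plausibility trimming,
    iterative connectivity filtering, restricted maximum likelihood (REML)
    fitting of a two-way (accession + year) linear mixed model with
    year-specific residual variances, campaign-level outlier removal by
    standardized coefficients of variation, point-level outlier removal by
    Bonferroni-Holm adjusted standardized residuals, best linear unbiased
    estimates (BLUEs) of accession means, and entry-mean heritability.
    Includes a synthetic-data generator with known ground truth, and readers
    and writers for a MIAPPE-style tabular exchange layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    nlme,
    lme4,
    readxl,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
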