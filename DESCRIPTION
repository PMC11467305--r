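Package: pedscreen
Title: Pedigree-Based Germline Variant Prioritization and Functional Assay Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes dominant germline candidate variants in small disease
    pedigrees by a frequency / co-segregation / deleteriousness filter cascade,
    screens structural-variant events by per-group recurrence with control
    exclusion, and estimates validation-cohort carrier frequencies with exact
    binomial intervals. Companion quantitative models for functional follow-up
    assays are included: threshold differential expression with cross-cell-line
    intersection, hypergeometric gene-set over-representation, permutation-based
    gene set enrichment scores, single-hit Poisson limiting-dilution stem-cell
    frequency estimation, delta-delta-Ct relative expression, and ellipsoid
    tumor volume. A synthetic-data module generates pedigrees, genotypes,
    structural-variant tables, expression matrices and limiting-dilution
    outcomes with the statistical structure the analysis assumes, including a
    deterministic fixture reproducing the carrier patterns of a 15-member
    multiple-primary-lung-cancer family study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
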