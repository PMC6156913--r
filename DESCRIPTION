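Package: towse
Title: Optimally Weighted SNP-Set Tests for Gene-Environment Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Permutation score tests for detecting SNP-set by environment
    interaction effects of rare and common variants on quantitative or
    binary traits. Implements the test of the optimally weighted
    combination of SNP-environment interactions (TOW-SE) and its
    variable-weight extension (VW-TOW-SE), which mixes standardized
    rare- and common-variant statistics over a convex weighting grid and
    takes the minimum p-value with a permutation correction. Includes
    genotype and phenotype input handling (VCF or plain dosage tables),
    covariate residualization, a reproducible permutation engine, and a
    haplotype-pool simulator with Type I error and power experiment
    runners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
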