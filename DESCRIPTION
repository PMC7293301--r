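Package: svdosage
Title: Dosage and Regulatory Effects of Rare Structural Variants on Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates rare structural variants (SVs) against genic and
    cis-regulatory elements (exons, promoters, linked enhancers, CTCF
    sites, TADs), quantifies their transcriptional consequences as
    relative expression and carrier z-scores, tests for selection via
    length-matched allele-frequency comparisons and singleton
    proportions, fits a joint linear model of expression z-scores on SV
    dosage covariates, and aggregates predicted per-gene effects into an
    intolerance-weighted regulatory disruption score for copy-number
    variant prioritization. Includes a self-contained synthetic-study
    generator (annotation, SV callset, expression, intolerance, two
    cohorts) so the full pipeline is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
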