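Package: cnvmod
Title: Genome-Wide CNV Modifier Analysis for Mutation Carrier Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of copy-number deletions as modifiers of
    breast and ovarian cancer risk in cohorts of BRCA1 pathogenic-variant
    carriers ascertained through case-enriched sampling. Provides consensus
    CNV calling from SNP-array Log R Ratio and B-allele-frequency signals
    (a distance-aware hidden Markov model caller and an independent binary
    segmentation caller, merged with configurable consensus filters),
    transcript-union gene-interval overlap to delineate deletion loci, a
    retrospective-likelihood one-degree-of-freedom score test of carrier
    status against censored age-at-onset outcomes with score-based
    relative-risk approximation, discrete-statistic false-discovery-rate
    control with a minimum-deletion-count filter, validation-concordance
    metrics, and a synthetic-data generator with known truth covering probe
    grids, intensity signals, deletion genotypes and two-stratum ascertained
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
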