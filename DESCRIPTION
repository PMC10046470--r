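Package: hmakit
Title: Pharmacogenomic and Methylome Analysis of Hypomethylating Agents
Version: 0.1.0
Authors@R:
    person("Maintainer", "hmakit", email = "hmakit@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for profiling the activity of
    hypomethylating agents (HMAs) across cancer cell line panels. Computes
    dose-response sensitivity metrics (normalized AUC, four-parameter logistic
    IC50) and tissue-enrichment odds ratios; converts methylation array
    intensities to beta-values and calls differentially methylated CpGs between
    treated and control triplicates at nested delta-beta thresholds; annotates
    CpG probes with chromatin marks and replication-timing classes; screens
    expression, mutation and promoter-methylation features for association with
    responder status under a lineage covariate, with a permutation-validated
    region-set score; scores drug-combination dose matrices with the
    Chou-Talalay combination index; and ships a seeded synthetic multi-omic
    data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
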