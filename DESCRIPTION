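Package: metamodule
Title: Multi-Cohort Survival Meta-Analysis and Seed-Gene Co-Expression
    Modules for Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Meta-analytic screening of a chromosomal-locus gene set for
    genes whose expression predicts patient survival across independent
    tumor cohorts (per-cohort Cox regression pooled with the
    DerSimonian-Laird random-effects estimator), derivation of seed-gene
    co-expression modules by Fisher-z meta-analysis of per-cohort Pearson
    correlations, scoring of up/down-tag pathway-activation signatures
    against expression profiles, and export of connectivity-map-style
    drug-reversal queries from seed-stratified differential-expression
    contrasts.  Includes a synthetic multi-cohort generator with planted
    prognostic genes and a planted latent-factor co-expression module so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
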