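Package: editscan
Title: Replicated Differential RNA-Editing Analysis with Marker Selection
    and Proteome Integration
Version: 0.1.0
Authors@R: person("editscan", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects differential RNA editing between two replicated sample
    groups using binomial likelihood-ratio (Wilks) confidence intervals and
    confidence-interval-weighted least-squares regression with a 3-standard-
    deviation significance rule; classifies sites as hyper- or hypo-edited
    and summarizes affected genes against curated annotation panels.  Also
    provides an iterative random-forest marker-gene selection procedure with
    leave-one-out linear-discriminant validation and PCA projection, SILAC
    heavy/light peptide-to-protein ratio pooling with proteome/transcriptome
    integration filters, and seeded synthetic-data generators (beta-binomial
    pileups, two-group expression matrices, multi-peptide SILAC tables) with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
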