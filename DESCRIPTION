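Package: mirseed
Title: Plant Small-RNA miRNA Discovery, Target Prediction and Degradome
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plant small-RNA sequencing analysis
    as applied to cereal seed development: read cleaning and length profiling,
    ordered reference-based tag classification, known-miRNA identification by
    precursor and mature-overlap alignment rules, novel-miRNA calling from
    genome-excised fold-back precursors filtered on hairpin geometry and the
    minimal folding energy index (MFEI), miRNA target prediction under the
    six plant complementarity rules with a duplex free-energy ratio
    criterion, degradome (PARE) tag mapping and cleavage-site validation,
    tag-count expression quantification (TPM), Audic-Claverie and Fisher
    differential-expression tests, hypergeometric term enrichment, and
    delta-delta-Ct relative quantification.  Includes a synthetic-data
    generator that plants known miRNAs, target sites and cleavage signals so
    every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
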