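Package: immunoEQA
Title: Scoring and Aggregation for Immunogenetics External Quality
    Assessment Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for running interlaboratory comparison (external quality
    assessment / proficiency testing) evaluations in histocompatibility and
    immunogenetics. Parses and compares HLA, KIR and HPA typing results
    including ambiguity lists and null-allele expression suffixes; assigns
    per-sample reference or consensus values (75%/95% antibody consensus
    rules and the ISO 13528 Annex C robust location/scale algorithm for
    quantitative chimerism); classifies laboratory errors into a taxonomy
    (null-allele, homozygosity, allele mismatch, specificity, quantification,
    interpretation); aggregates success rates by scheme, year and analytical
    family; and generates seeded synthetic laboratory reports with error
    injection so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
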