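Package: dfurepo
Title: Transcriptomics-Driven Drug Repositioning for Diabetic Foot Ulcer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a transcriptomics-driven
    drug-repositioning pipeline for diabetic foot ulcer: per-cohort
    differential expression with empirical-Bayes moderated t-statistics
    (paired and unpaired designs), cross-cohort DEG intersection,
    protein-protein-interaction network expansion of the overlap set,
    hypergeometric over-representation analysis across six functional
    annotation categories with a 0-6 gene prioritization score, and mapping
    of the resulting biological risk genes to approved drugs with defined
    interaction types. Ships a synthetic-data generator that plants ground
    truth in every input artifact so the entire pipeline is exercisable and
    verifiable without any download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
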