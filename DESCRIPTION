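Package: fusescore
Title: Confidence Scoring and Artifact Filtering for RNA-Seq Fusion Gene Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based confidence scoring for putative fusion transcripts
    called from paired-end RNA-seq. Reads fusion-candidate tables in the
    deFuse output dialect, assigns each candidate a confidence score by
    summing curated feature weights onto a baseline, builds a blacklist of
    gene pairs recurrently called across unrelated tumour entities, and
    classifies candidates into high-, medium- and low-confidence tiers.
    Includes a seeded synthetic-cohort generator with known truth labels so
    every scoring rule can be exercised without access to sequencing data,
    plus recovery-rate evaluation against lists of validated fusions and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
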