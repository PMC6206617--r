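Package: invivoclass
Title: Identification, Classification and Evaluation of In Vivo Pharmacology Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation pipeline for in vivo pharmacology assay records of the kind
    held in large bioactivity databases. Identifies disease-, phenotype- and
    toxicity-relevant in vivo assays from flat tabular assay metadata (BioAssay
    Ontology format, organism class, assay type and source filters), annotates
    assay descriptions with a three-level assay classification via a curated
    regular-expression pattern dictionary distinguishing reference animal models
    from phenotype endpoints, projects classifications onto MeSH descriptor
    terms, computes corpus coverage statistics and frequency breakdowns, and
    evaluates annotations against a curator gold standard with confusion-matrix
    statistics. Includes a deterministic synthetic-corpus generator with planted
    ground truth so the whole pipeline is testable without a database connection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
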