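Package: sctforge
Title: SNOMED CT Expressions, EL++ Reasoning, and an OGMS-Aligned Upper-Level Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning SNOMED CT content into a formally consistent
    OWL 2 ontology. Reads and writes RF2-style snapshot tables (concepts,
    descriptions, relationships), parses compositional-grammar expressions
    (including refinements, attribute groups, nested expressions, and
    concrete values), translates them into a lightweight EL++ description
    logic with role groups, classifies terminologies by completion-rule
    saturation, eliminates redundant grouped restrictions, and emits an
    upper-level ontology scaffold aligned with the Ontology for General
    Medical Science (OGMS) in OWL 2 functional or Manchester syntax, with
    relationship rows reified as first-class individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
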