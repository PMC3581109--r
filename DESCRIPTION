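Package: agemine
Title: Mining Age-Phenotype Evidence from MEDLINE Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based text-mining pipeline that extracts age and age-range
    mentions from MEDLINE-format abstracts, assigns one of five age-phenotype
    relationship types (onset, diagnosis, observation, occurrence, evaluation),
    builds whole-sentence evidence snippets, maps them to disease-ontology and
    concept-lexicon terms by perfect-match search, and stores the resulting
    evidence instances in a queryable knowledge base. Includes an evaluation
    harness scoring each pipeline stage against gold annotations, hierarchical
    clustering of diseases by their literature age profiles, and a seeded
    synthetic-corpus generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
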