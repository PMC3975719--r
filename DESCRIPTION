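Package: RxReasoner
Title: Terminology-Graph Reasoning for Drug Indication and Contraindication Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-layer clinical decision-support engine for drug
    recommendation discovery. Coded patient records (ICD-10 diseases, ATC/UNII
    drug codes, substance names) are first enriched against a SKOS-style
    terminology graph -- broader-transitive closure over the code hierarchies,
    membership in expert-defined concept collections, and closeMatch code
    equivalence -- and the enriched record is then matched against a boolean
    rule base of substance indications and contraindications. Rules use and/or
    logic with demographic (age group, sex group) constraints; they can be
    evaluated directly or after OR-elimination into conjunctive form, with a
    two-phase rule-selection strategy (demographic filter, then premise-term
    overlap) that is provably sound for the negation-free rule language.
    Contraindications take precedence over indications in the final
    recommendation list. Includes loaders for a terminology TSV dialect,
    concept-collection and rule-file dialects, SKOS Turtle import/export,
    deterministic synthetic fixture generators, and cohort-level quality
    evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
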