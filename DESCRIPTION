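Package: rarelink
Title: Weakly Supervised Rare-Disease Phenotyping from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies rare-disease phenotypes from candidate mention-concept
    links extracted from clinical notes. Candidate mention-UMLS links are weakly
    labelled by two rules (a mention character-length rule and a concept
    prevalence rule, combined by XNOR selection and AND labelling), represented
    as span-pooled contextual mention vectors, filtered by a logistic phenotype
    confirmation model, and mapped to Orphanet (ORDO) rare-disease concepts
    through relation- and phenome-filtered ontology cross-references.
    Text-derived admission cohorts can be compared against ICD-code-derived
    cohorts. Includes a seeded synthetic corpus generator and a deterministic
    stub encoder so the full pipeline is testable without clinical data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
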