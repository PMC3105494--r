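Package: alignaudit
Title: Logic-Based Auditing and Repair of Cross-Ontology Equivalence
    Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Audits equivalence mappings between independently developed
    biomedical terminologies (UMLS-Metathesaurus style).  Extracts
    cross-source mappings from MRCONSO-like RRF files by concept unique
    identifier (CUI), detects mapping conflicts with a conservativity
    check and a disjointness-based incoherence heuristic over a sound
    structural reasoner, scores conflicting mappings by the overlap of
    their locality-based modules (with lexical augmentation), and repairs
    conflict sets by a minimal-total-confidence diagnosis.  Includes a
    synthetic fixture generator with planted errors so the whole pipeline
    is testable without licensed UMLS data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
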