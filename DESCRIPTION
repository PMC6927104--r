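Package: cdemapr
Title: Map ISO 11179 Common Data Elements to BRIDG Classes by Lexical
    Similarity Weight Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated mapping of ISO 11179 Common Data Elements
    (CDEs) to candidate classes of the Biomedical Research Integrated
    Domain Group (BRIDG) domain model. Six CDE text attributes (long
    name, object class, property, value domain long name, representation
    term, question text) are compared with an edit-distance word
    similarity and a greedy similarity-matrix reduction; the six
    attribute weights are learned by a single-layer delta-rule network
    trained by gradient descent on within-class versus between-class
    average similarities; a top-k recommender ranks candidate classes
    for a query CDE. Includes readers and writers for a flat CSV/JSON
    corpus schema, a best-effort reader for caDSR CDE Browser XML
    exports, a seeded generator of class-structured synthetic corpora,
    an evaluation harness (top-n match rate, parameter sweeps, DEC
    concept overlap), and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
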