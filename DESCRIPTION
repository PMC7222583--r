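Package: minipredicate
Title: Rule-Based Extraction of Semantic Predications from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts subject-PREDICATE-object semantic predications from
    biomedical sentences using shallow (minimal-commitment) parsing, a
    pluggable knowledge base of concepts and semantic types, indicator rules
    that map lexical and structural triggers to predicates, and an ontology of
    licensed semantic-type triples. Supports hypernymic and comparative
    predications, negation detection, noun-phrase coordination, sortal
    anaphora resolution, sentence-level inference rules, and domain
    extensions, with plain-text, full-fielded, and XML output formats. Ships
    a bundled miniature knowledge base and a synthetic full-scale resource
    generator for loader validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
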