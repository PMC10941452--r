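Package: annostore
Title: Stand-Off Biomedical Text Annotation Store with Agreement and Automatic Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, file-backed store for stand-off annotation of
    biomedical text by multiple annotators over multiple rounds. Supports five
    annotation types (mentions, concept links, relationships, assertions,
    document labels) over an ontology-agnostic concept registry, computes
    inter-annotator agreement (Fleiss' and Cohen's kappa, strict-majority
    consensus), annotation statistics and baseline-diff provenance, and
    exchanges annotations in JSON, CSV and BioC-XML. Includes a pluggable
    automatic-annotation pipeline (lexicon entity linking, sentence splitting,
    multi-instance bags, rule-based predicate scoring) for gene-disease and
    gene-expression-cancer association extraction, and seeded synthetic
    corpus/annotator generators for controlled agreement experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
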