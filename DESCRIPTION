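Package: trackmeta
Title: Exchange, Validation and Augmentation of Genomic Track Metadata
Version: 0.1.0
Authors@R:
    person("trackmeta", "developers", email = "trackmeta@example.org",
           role = c("aut", "cre"))
Description: A draft exchange standard for genomic track metadata built
    around six linked object types (document info, track collection, study,
    sample, experiment, track), together with the tooling such a standard
    needs: a JSON Schema (draft 7) emitter extended with document-set
    keywords for uniqueness, foreign references, compact identifiers
    (CURIEs) and ontology ancestor constraints; a validator that enforces
    those rules against offline registry snapshots; an augmentation step
    that derives human-readable labels, ontology versions, summary fields
    and provenance stamps from minimally filled documents; converters
    between UCSC-style track-hub text metadata, the document model and a
    tabular track-collection (GSuite dialect) format; deterministic fixture
    generators; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
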