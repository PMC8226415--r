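---
title: "trackmeta: model, validation and augmentation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trackmeta: model, validation and augmentation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmeta)
```

## The problem and the model

Track files are the condensed end products of genomics pipelines; their
usefulness downstream depends almost entirely on metadata that file
formats do not carry. `trackmeta` implements an exchange document holding
six object types — document info, track collection, study, sample,
experiment, track — as flat lists linked by local identifiers. A
hierarchical nesting was deliberately avoided: a sample serves multiple
experiments, an experiment yields multiple tracks, and an aggregated
track (e.g. a consensus peak set) traces to multiple samples, so the
relations form a graph, not a tree. Multiplicity towards samples is
expressed through experiment-to-experiment `aggregated_from` links
rather than a multi-valued sample reference; this keeps the
"exactly one of sample link / aggregation links" constraint checkable
per experiment and gives stepwise provenance for in-silico analyses.

The model is rendered as a JSON Schema (draft 7) by `emit_schema()`.
Document-set semantics that schema dialects cannot express are encoded as
extension keywords interpreted by this package's validator: `x_unique`,
`x_foreign_ref`, `x_curie_prefixes`, `x_ontology_ancestors`, `x_doi`,
`x_url_schemes`, `x_augmented`. One internal descriptor table generates
both the schema text and the structural checks, so the two cannot drift.

Design choices where the design was genuinely open:

* **Multiple collections per document** are allowed (everything is a
  list). The alternative — one collection per document, identified by the
  document DOI — creates an impractically fine granularity of published
  documents, so it was rejected.
* **Tracks carry a required `experiment_ref`**: every track is generated
  by an experiment, physical or in-silico.
* **`aggregated_from` is restricted to in-document references.**
  Cross-document provenance belongs in `derived_from` at document level.
* **Vocabulary seeds.** `type_of_condensed_data` ships with eight values
  (broad/narrow/gapped peaks, signal intensities, fold change, sequence
  variants, methylation fraction, gene expression levels) and
  `genomic_track_type` with the eight geometric track types (points,
  valued points, segments, valued segments, genome partition, step
  function, function, linked segments). Both are explicitly replaceable
  starting points, kept in-schema because no public ontology currently
  provides such terms.
* **`biospecimen_class`** is a closed set of exactly the four
  `sample_type` children (cell line, cell type, abnormal cell type,
  organism part), making the class-selects-child rule total.

## Registries without a network

Validation needs an identifier resolver, an assembly name service and
ontology lookups. All three are replaced by offline tables with the same
semantics (`make_fixture_registries()`, serialized under
`inst/extdata/registries/`, swappable via `load_registries()` /
`--registry-dir`):

* a CURIE prefix registry (prefix, anchored accession pattern, URL
  template) with seven prefixes including `insdc.gca`, a taxonomy and a
  publication prefix;
* an assembly synonym table pairing reference-consortium names with
  browser synonyms and the chromosome-naming scheme each name implies
  (`GRCh37`/`hg19`, `GRCh38`/`hg38`, `GRCm38`/`mm10`, `GRCm39`/`mm39`),
  each carrying its assembly accession CURIE;
* three versioned ontology snapshots, DAGs with multiple roots:
  `toa` (assays, data formats, biological target entities), `tos`
  (biospecimens and phenotypes), `tod` (data-use conditions). Fixture
  IRIs live under the reserved base `https://onto.invalid/` so they can
  never collide with real ontologies. Cycles are rejected at load.

The packaged tables cannot certify that a prefix is actually registered
with a live resolver — they check syntax and registry semantics only;
dropping in tables exported from the real services is the intended
configuration point.

## Validation

`validate_document()` accumulates issues (never fail-fast) across:
structure (required fields, types, enums, date/URL/email shapes),
local-id uniqueness, foreign references, `aggregated_from` acyclicity
(an experiment is flagged iff it lies on a directed cycle), CURIE syntax
/ prefix / accession-pattern, ontology term existence / required-ancestor
descent / label consistency, assembly consistency (the `annotation_name`
must be the canonical name or a registered synonym of the assembly named
by `assembly_id`), checksum digest length by method (md5 32 / sha1 40 /
sha256 64 lowercase hex), DOI syntax, the sample-XOR-aggregation rule,
and the biospecimen-class child rule. Reports are deterministic: issues
are sorted by (path, rule kind), paths are JSON-pointer style with
zero-based indices, `ok` is true iff the issue list is empty.

Two reading choices worth recording. First, ontology labels are
augmentation-owned, so an *absent* label is never an issue; a *present*
label must equal the snapshot label exactly, whether or not the document
has been augmented — a present-but-wrong label is always a curation
error. Second, augmentation-owned fields (`term_label`, the two summary
fields, `ontology_versions`, `augmented_from`) are excluded from the
schema's `required` arrays even where the attribute tables list them,
because a minimal pre-augmentation document must validate; the augmenter
is their owner and always produces them.

Unknown fields anywhere in the tree are preserved verbatim and never
validated: batch-converted repository metadata keeps all its
non-conforming fields.

## Augmentation

`augment_document()` refuses invalid input (listing the blocking issues)
and then, in order: fills absent `term_label`s from the snapshots; writes
`doc_info.ontology_versions` as exactly the versions of the snapshots
whose terms occur in the document (set equality, recomputed every run);
fills `sample_type.summary` (the label of the child selected by
`biospecimen_class`) and `target.summary`; and stamps
`doc_info.augmented_from` with the document's DOI, falling back to its
version id. Labels and summaries are only filled when absent, so
submitted content is never altered and the operation is idempotent.

The target summary recipe is selected by classifying the experiment's
technique term against a priority-ordered rule table
(`inst/extdata/technique_rules.tsv`, data not code): descendants of the
immunoprecipitation branch use the gene recipe (gene label, then a single
space plus `target_details` when non-empty — e.g. `CTCF phosphorylated`);
descendants of the sequence-feature-detection branch use the
`sequence_feature` label; genotyping-branch techniques use the
`phenotype` label; everything else is untargeted and yields the empty
string. Only the gene rule has an authoritative precedent (ChIP-seq
transcription-factor experiments annotated with an HGNC gene id); the
other rows are provisional and marked as such here. The gene label falls
back to the CURIE accession when no label was supplied, since no gene
registry snapshot is packaged.

## Converters

**GSuite dialect** (tabular track collection): optional `#` comment
preamble, a header line starting `###` with tab-separated column names,
first column `uri`; one tab-separated row per track; `.` for missing.
Columns: uri, title, genome, file_format, track_type,
condensed_data_type, technique, target_summary, sample_summary,
study_name, source_collection. `from_gsuite()` reconstructs the track
subset (URI, title, genome and track type round-trip exactly) plus a
single synthetic collection; other objects are stubs.

**Track hub import** parses blank-line-separated key/value stanzas
(key = first whitespace token, indentation flattened). The hub stanza
becomes a collection; each leaf trackDb stanza with a `bigDataUrl`
becomes a track; container stanzas (those named as a `parent`) and
URL-less leaves are logged, not emitted. `metadata` key=value pairs
are retained as unknown fields. Genome names recognised by the assembly
registry also set `assembly_id`; unrecognised ones are kept verbatim and
logged. The result is deliberately a *draft*: it fails validation with
exactly the missing-required issues that enumerate the curation work,
and the import log lists them in prose. UCSC's full settings grammar
(includes, `parent` view hierarchies, per-view settings) is out of scope.

## Fixture generators and what a green test establishes

`make_valid_document(seed, ...)` draws every object from the fixture
registries under a single integer seed (the caller's RNG state is saved
and restored). Defaults are modest (1 collection, 2 studies, 3 samples,
5 experiments, 6 tracks) so hundred-seed sweeps stay fast. About 20% of
experiments are aggregation-based, with a guaranteed chain of length two
or more whenever there are at least three experiments; about 10% of
objects carry unknown extra fields; 70% of term pairs include their
label (the rest exercise augmentation); dates, digests, accessions and
URLs are synthesized. `make_invalid_document(seed, kind)` injects exactly
one minimal violation per validator rule kind (all kinds except `schema`,
whose violations are structural and covered by dedicated tests).

The generator emulates the *shape* of curated track-collection metadata,
not its content: labels are synthetic, all samples are human, techniques
come from a small pool, and file URLs do not resolve. A green suite
therefore establishes the correctness of the model, validator, augmenter
and converters on well-formed and minimally-broken documents — not
robustness against the heterogeneity of real repository metadata.

## Numerical and procedural choices

* Canonical serialization: keys sorted (C-locale radix order) at every
  level, two-space indent, UTF-8, trailing newline; arrays keep order.
  Dump/load is the identity on the model, so byte-identical dumps are the
  document equality used everywhere.
* Cycle and descendant checks are plain frontier searches; tests verify
  both against an independent boolean matrix transitive-closure oracle.
* `is_descendant()` is reflexive-false; ancestor constraints accept the
  ancestor term itself only via the explicit `term_id == ancestor` case
  in the validator, so using a branch root as a value is rejected.
* DOI validation: strip optional `doi:` scheme and whitespace, then
  require `10.<digits>/<suffix>`.
* CLI exit codes: 0 ok, 1 validation failure, 2 usage, 3 I/O or
  configuration.

## Known limitations

* No live resolution of CURIEs, assemblies or ontology terms; the
  fixture registries assert syntax and internal consistency only.
* Sequence-collection checksum identifiers for assemblies are not
  supported; `assembly_id` is an accession CURIE.
* Technique rules beyond the gene recipe are provisional; over-complete
  targets (children not demanded by the technique) are not flagged.
* The GSuite export is lossy by design (a tabular view); only the track
  subset round-trips.
* Empty JSON objects and arrays that are *unknown* fields both survive
  round trips, but an unknown empty object is indistinguishable from an
  empty array only by its parsed representation, not re-inspected later.
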