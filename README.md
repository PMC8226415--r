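# trackmeta

Genomic tracks — peak calls, signal profiles, variants or expression
levels positioned on the coordinates of a reference genome assembly, and
usually shipped as BigWig / BigBed / BCF files — carry notoriously poor
metadata: free-text labels, ambiguous assembly names ("hg19" vs "GRCh37"),
no machine-readable link back to the sample, assay or raw data. That makes
them hard to find, hard to combine across repositories, and risky to
re-analyse.

`trackmeta` implements a draft exchange standard for genomic track
metadata, plus the tooling such a standard needs. It is aimed at data
producers annotating track collections (e.g. a track hub) for reuse, and
at tool developers consuming harmonized collections downstream.

## The model

A metadata *document* holds flat lists of six object types linked by local
identifiers:

```
doc_info     version/provenance of the document itself
collection   the outer grouping scope (maps 1:1 to a track hub)
study   <--- experiment ---> sample
                 ^  \
                 |   `-- aggregated_from: provenance chain of upstream
              track      (in-silico) experiments, a DAG
```

Four core entity types sit between the document root and the file level:
**study**, **sample**, **experiment** and **track**. Every controlled
value is an *ontology term pair* — term IRI plus human-readable label —
and every external reference is a CURIE (`prefix:accession`) resolvable
through a prefix registry. Two novel closed vocabularies live directly in
the schema: `type_of_condensed_data` (what the condensed data means, e.g.
"broad peaks") and `genomic_track_type` (the track's geometry, e.g.
"valued segments"). Formally the model is emitted as a JSON Schema
(draft 7) extended with document-set keywords (`x_unique`,
`x_foreign_ref`, `x_curie_prefixes`, `x_ontology_ancestors`,
`x_augmented`) that plain JSON Schema cannot express.

Validation (`validate_document()`) checks schema conformance plus
uniqueness of local ids, foreign-reference existence, acyclicity of
`aggregated_from`, CURIE syntax/prefix/accession, ontology term existence,
ancestor constraints and label consistency, assembly-name consistency
(`annotation_name` vs `assembly_id`), checksum and DOI formats, the
sample/aggregation exactly-one-of rule, and the biospecimen-class child
rule. Augmentation (`augment_document()`) then fills everything a machine
can derive: ontology labels, the versions of every ontology actually
referenced, the two merged summary fields (`sample_type.summary`,
`target.summary`), and an `augmented_from` provenance stamp.

## Worked example

```r
library(trackmeta)

d <- make_valid_document(42, n_tracks = 2)   # deterministic fixture
validate_document(d)
#> validation OK: 0 issues

a <- augment_document(d)
a$samples[[1]]$sample_type$summary
#> [1] "GM12878"
unlist(a$doc_info$ontology_versions)
#>          toa          tod          tos
#> "2021-03-12"        "1.2" "2021-02-19"

cat(format_gsuite(to_gsuite(a)))
#> ###uri	title	genome	file_format	track_type	condensed_data_type	technique	target_summary	sample_summary	study_name	source_collection
#> https://hub.example.org/s42/track_1.bw	Track 1	hg38	BigWig	step function	fold change	ATAC-seq assay	.	.	Chromatin state study 2	Regulatory element collection 1
#> https://hub.example.org/s42/track_2.bb	Track 2	hg38	BigBed	step function	signal intensities	ATAC-seq assay	.	.	Chromatin state study 2	Regulatory element collection 1

validate_document(make_invalid_document(42, "foreign_ref"))
#> validation FAILED: 1 issue(s)
#>   [foreign_ref] /experiments/0/sample_ref: 'sample_does_not_exist' does not name any sample local_id
```

The first GSuite line is the `###` header whose first column is always the
track URI; `.` marks a value the document does not (yet) provide — here the
summary columns are empty because both tracks come from an untargeted
(ATAC-seq) experiment. Validation reports address nodes by JSON-pointer
style paths with zero-based indices.

A command-line interface wraps the same functions
(`system.file("cli", "trackmeta", package = "trackmeta")`):
`validate` (exit 0 iff valid), `augment`, `convert --to gsuite|json`,
`import-hub`, `gen-fixture`. Registries default to the packaged offline
fixtures; point `--registry-dir` at your own TSV tables to swap in real
services.

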