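# The document model: six linked object types cross-referenced by local
# identifiers.  A single table of field descriptors drives both the emitted
# JSON Schema and the validator's structural checks, so the two cannot
# drift apart.  Documents themselves are plain nested lists mirroring the
# JSON tree; unknown fields are ordinary list entries and survive all
# transformations verbatim.

onto_base <- "https://onto.invalid/"

#' Build a fixture-ontology IRI
#' @param ns namespace (e.g. "TOA"), @param n term number.
#' @noRd
onto_iri <- function(ns, n) sprintf("%s%s_%07d", onto_base, ns, n)

# Closed in-schema vocabularies.  The two track-level sets are novel
# controlled vocabularies of this standard (condensed-data semantics and
# geometric track typing); both are starting points meant to be replaced by
# ontology terms once such terms exist.
tm_vocab <- function(which) {
  switch(which,
    type_of_condensed_data = c(
      "broad peaks", "narrow peaks", "gapped peaks", "signal intensities",
      "fold change", "sequence variants", "methylation fraction",
      "gene expression levels"),
    genomic_track_type = c(
      "points", "valued points", "segments", "valued segments",
      "genome partition", "step function", "function", "linked segments"),
    checksum_method = c("md5", "sha1", "sha256"),
    stop("unknown vocabulary ", which)
  )
}

# biospecimen_class is a closed set of four ontology terms; the class value
# selects which sample_type child must be present.
biospecimen_classes <- function() {
  data.frame(
    term_id = c(onto_iri("TOS", 2), onto_iri("TOS", 6),
                onto_iri("TOS", 11), onto_iri("TOS", 14)),
    label = c("cell line", "cell type", "abnormal cell type", "organism part"),
    child = c("cell_line", "cell_type", "abnormal_cell_type", "organism_part"),
    stringsAsFactors = FALSE)
}

checksum_lengths <- c(md5 = 32L, sha1 = 40L, sha256 = 64L)

# --- field descriptor constructors -----------------------------------------

f_str    <- function(required = FALSE, augmented = FALSE, enum = NULL)
  list(type = "string", required = required, augmented = augmented, enum = enum)
f_url    <- function(required = FALSE) list(type = "url", required = required)
f_email  <- function(required = FALSE) list(type = "email", required = required)
f_date   <- function(required = FALSE) list(type = "date", required = required)
f_doi    <- function(required = FALSE) list(type = "doi", required = required)
f_curie  <- function(required = FALSE, prefixes = "*")
  list(type = "curie", required = required, prefixes = prefixes)
f_term   <- function(required = FALSE, snapshot = NULL, ancestors = NULL,
                     id_enum = NULL)
  list(type = "term_pair", required = required,
       binding = if (!is.null(snapshot))
         list(snapshot = snapshot, ancestors = ancestors),
       id_enum = id_enum)
f_obj    <- function(fields, required = FALSE)
  list(type = "object", required = required, fields = fields)
f_arr    <- function(item, required = FALSE, min_items = NULL)
  list(type = "array", required = required, item = item, min_items = min_items)
f_map    <- function(required = FALSE, augmented = FALSE)
  list(type = "map_string", required = required, augmented = augmented)
f_ref    <- function(target, required = FALSE)
  list(type = "ref", required = required, target = target)

#' The model's field descriptors
#'
#' Returns, per object type, the named list of field descriptors that
#' defines the exchange model.  Used internally by [emit_schema()] and the
#' validator; exported for introspection.
#'
#' @return A named list of object descriptors.
#' @export
model_spec <- function() {
  bios <- biospecimen_classes()

  contact <- f_obj(required = TRUE, fields = list(
    name  = f_str(required = TRUE),
    email = f_email(required = TRUE),
    url   = f_url()))

  sample_type <- f_obj(required = TRUE, fields = list(
    cell_line          = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 2)),
    cell_type          = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 6)),
    abnormal_cell_type = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 11)),
    organism_part      = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 14)),
    summary            = f_str(augmented = TRUE)))

  target <- f_obj(required = TRUE, fields = list(
    gene_id = f_obj(fields = list(
      id    = f_curie(required = TRUE, prefixes = "hgnc"),
      label = f_str())),
    gene_product_type       = f_term(snapshot = "toa", ancestors = onto_iri("TOA", 201)),
    macromolecular_structure = f_term(snapshot = "toa", ancestors = onto_iri("TOA", 204)),
    phenotype               = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 100)),
    sequence_feature        = f_term(snapshot = "toa", ancestors = onto_iri("TOA", 206)),
    target_details          = f_str(),
    summary                 = f_str(augmented = TRUE)))

  checksum <- f_obj(required = TRUE, fields = list(
    method = f_str(required = TRUE, enum = tm_vocab("checksum_method")),
    value  = list(type = "checksum_value", required = TRUE)))

  list(
    doc_info = list(
      local_id          = f_str(required = TRUE),
      version_id        = f_str(required = TRUE),
      version_date      = f_date(required = TRUE),
      ontology_versions = f_map(augmented = TRUE),
      source_url        = f_url(required = TRUE),
      doi               = f_doi(required = TRUE),
      derived_from      = f_str(),
      augmented_from    = f_str(augmented = TRUE)),
    collection = list(
      local_id    = f_str(required = TRUE),
      name        = f_str(required = TRUE),
      description = f_str(required = TRUE),
      source_url  = f_url(required = TRUE),
      contact     = contact),
    study = list(
      local_id       = f_str(required = TRUE),
      collection_ref = f_ref("collections", required = TRUE),
      name           = f_str(required = TRUE),
      publications   = f_arr(f_curie(prefixes = "pubmed"), required = TRUE),
      contact        = contact),
    sample = list(
      local_id          = f_str(required = TRUE),
      species           = f_curie(required = TRUE, prefixes = "taxonomy"),
      biospecimen_class = f_term(required = TRUE, snapshot = "tos",
                                 ancestors = onto_iri("TOS", 1),
                                 id_enum = bios$term_id),
      sample_type       = sample_type,
      phenotype         = f_term(snapshot = "tos", ancestors = onto_iri("TOS", 100)),
      external_refs     = f_arr(f_curie())),
    experiment = list(
      local_id        = f_str(required = TRUE),
      study_ref       = f_ref("studies", required = TRUE),
      sample_ref      = f_ref("samples"),
      aggregated_from = f_arr(f_ref("experiments")),
      technique       = f_term(required = TRUE, snapshot = "toa",
                               ancestors = onto_iri("TOA", 1)),
      target          = target,
      lab_protocol_description     = f_str(required = TRUE),
      compute_protocol_description = f_str(required = TRUE)),
    track = list(
      local_id        = f_str(required = TRUE),
      source_coll_ref = f_ref("collections", required = TRUE),
      experiment_ref  = f_ref("experiments", required = TRUE),
      file_url        = f_url(required = TRUE),
      label_short     = f_str(required = TRUE),
      label_long      = f_str(required = TRUE),
      description     = f_str(required = TRUE),
      assembly_id     = f_curie(required = TRUE, prefixes = "insdc.gca"),
      annotation_name = f_str(required = TRUE),
      raw_file_ids    = f_arr(f_curie(), required = TRUE),
      file_format     = f_term(required = TRUE, snapshot = "toa",
                               ancestors = onto_iri("TOA", 100)),
      type_of_condensed_data = f_str(required = TRUE,
                                     enum = tm_vocab("type_of_condensed_data")),
      genomic_track_type     = f_str(required = TRUE,
                                     enum = tm_vocab("genomic_track_type")),
      checksum            = checksum,
      data_use_conditions = f_arr(f_term(snapshot = "tod",
                                         ancestors = onto_iri("TOD", 1))),
      data_use_url        = f_url())
  )
}

# Mapping between document list names and schema definition names.
doc_lists <- c(collections = "collection", studies = "study",
               samples = "sample", experiments = "experiment",
               tracks = "track")

# ---------------------------------------------------------------------------
# Schema emission

render_field <- function(desc) {
  aug <- isTRUE(desc$augmented)
  out <- switch(desc$type,
    string = {
      s <- list(type = "string")
      if (!is.null(desc$enum)) s$enum <- as.list(desc$enum)
      s
    },
    url = list(type = "string", format = "uri",
               x_url_schemes = list("http", "https", "ftp")),
    email = list(type = "string", format = "email"),
    date = list(type = "string", format = "date"),
    doi = list(type = "string", x_doi = TRUE),
    curie = list(type = "string", x_curie_prefixes = as.list(desc$prefixes)),
    checksum_value = list(type = "string", pattern = "^[0-9a-f]+$"),
    ref = list(type = "string",
               x_foreign_ref = sprintf("/%s/*/local_id", desc$target)),
    term_pair = {
      id_schema <- list(type = "string")
      if (!is.null(desc$id_enum)) id_schema$enum <- as.list(desc$id_enum)
      s <- list(type = "object", required = list("term_id"),
                properties = list(
                  term_id = id_schema,
                  term_label = list(type = "string", x_augmented = TRUE)))
      if (!is.null(desc$binding)) {
        s$x_ontology_ancestors <- list(
          snapshot = desc$binding$snapshot,
          ancestors = as.list(desc$binding$ancestors))
      }
      s
    },
    map_string = list(type = "object",
                      additionalProperties = list(type = "string")),
    object = render_object(desc$fields),
    array = {
      s <- list(type = "array", items = render_field(desc$item))
      if (!is.null(desc$min_items)) s$minItems <- desc$min_items
      s
    },
    stop("unknown descriptor type ", desc$type)
  )
  if (aug) out$x_augmented <- TRUE
  out
}

render_object <- function(fields) {
  req <- names(fields)[vapply(fields, function(d)
    isTRUE(d$required) && !isTRUE(d$augmented), logical(1))]
  list(type = "object",
       required = as.list(req),
       properties = lapply(fields, render_field))
}

#' Emit the formal exchange schema
#'
#' Renders the model as a JSON Schema (draft-7 dialect) extended with
#' document-set keywords: `x_unique` (paths that must hold unique values),
#' `x_foreign_ref` (local-identifier reference targets),
#' `x_curie_prefixes` (allowed compact-identifier prefixes),
#' `x_ontology_ancestors` (term must descend from the listed IRIs) and
#' `x_augmented` (field is owned by the augmentation step).
#'
#' @return The schema as canonical JSON text.
#' @export
emit_schema <- function() {
  spec <- model_spec()
  defs <- lapply(spec, render_object)
  root_props <- list(doc_info = list("$ref" = "#/definitions/doc_info"))
  for (ln in names(doc_lists)) {
    root_props[[ln]] <- list(
      type = "array", minItems = 1,
      items = list("$ref" = paste0("#/definitions/", doc_lists[[ln]])))
  }
  fref <- list()
  for (ln in names(doc_lists)) {
    for (fn in names(spec[[doc_lists[[ln]]]])) {
      d <- spec[[doc_lists[[ln]]]][[fn]]
      if (d$type == "ref") {
        fref[[sprintf("/%s/*/%s", ln, fn)]] <-
          sprintf("/%s/*/local_id", d$target)
      } else if (d$type == "array" && d$item$type == "ref") {
        fref[[sprintf("/%s/*/%s/*", ln, fn)]] <-
          sprintf("/%s/*/local_id", d$item$target)
      }
    }
  }
  schema <- list(
    "$schema" = "http://json-schema.org/draft-07/schema#",
    title = "Genomic track metadata exchange document",
    type = "object",
    required = as.list(c("doc_info", names(doc_lists))),
    properties = root_props,
    definitions = defs,
    x_unique = as.list(sprintf("/%s/*/local_id", names(doc_lists))),
    x_foreign_ref = fref)
  canonical_json(schema)
}

# ---------------------------------------------------------------------------
# Reading and writing documents

#' Load a metadata document from JSON text
#'
#' Parses without validation; unknown fields anywhere in the tree are kept
#' verbatim so that batch-converted repository metadata loses nothing.
#'
#' @param text JSON text (a single string or a character vector of lines).
#' @return A document (nested list) of class `track_doc`.
#' @export
load_document <- function(text) {
  txt <- paste(text, collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      tm_error("parse", sprintf("malformed JSON: %s", conditionMessage(e)))
    })
  if (!is.list(doc) || is.null(names(doc))) {
    tm_error("structure", "top level of a document must be a JSON object")
  }
  structure(doc, class = "track_doc")
}

#' Serialize a document to canonical JSON
#'
#' Deterministic: keys sorted at every level, two-space indent, trailing
#' newline.  `load_document(dump_document(doc))` reproduces `doc`.
#'
#' @param doc a document as returned by [load_document()] or
#'   [make_valid_document()].
#' @return JSON text.
#' @export
dump_document <- function(doc) {
  canonical_json(doc)
}

#' Compare two documents for semantic equality
#'
#' Equality modulo canonical key ordering.
#'
#' @param a,b documents.
#' @return `TRUE` or `FALSE`.
#' @export
document_equal <- function(a, b) {
  identical(canonical_json(a), canonical_json(b))
}

#' @export
print.track_doc <- function(x, ...) {
  n <- vapply(names(doc_lists), function(ln) length(x[[ln]]), integer(1))
  cat(sprintf("<track_doc '%s': %s>\n",
              doc_get(x, c("doc_info", "local_id")) %||% "?",
              paste(sprintf("%d %s", n, names(doc_lists)), collapse = ", ")))
  invisible(x)
}
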