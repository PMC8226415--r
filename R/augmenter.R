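# Augmentation: the deterministic post-validation step that turns a
# minimally filled, machine-oriented document into one that is directly
# useful downstream.  It fills human-readable ontology labels, records the
# versions of every ontology snapshot actually referenced, computes the two
# merged summary fields, and stamps document provenance.  It never removes
# or alters submitted content; it only fills augmentation-owned slots.

#' Augment a valid document
#'
#' @param doc a document; must pass [validate_document()] unless
#'   `force = TRUE`.
#' @param registries a `registry_set` supplying ontology snapshots and the
#'   technique rule table context.
#' @param force skip the validity precondition (used by the CLI `--force`).
#' @return The augmented document.  Augmenting an already augmented
#'   document is a no-op (idempotence).
#' @export
augment_document <- function(doc, registries = default_registries(),
                             force = FALSE) {
  if (!force) {
    rep <- validate_document(doc, registries)
    if (!rep$ok) {
      tm_error("augmentation_refused",
               paste0("document is not valid; blocking issues:\n",
                      paste(vapply(rep$issues, function(i)
                        sprintf("  [%s] %s: %s", i$rule_kind, i$path, i$message),
                        character(1)), collapse = "\n")),
               report = rep)
    }
  }
  snaps <- registries$ontologies

  # 1. fill absent ontology labels
  used <- character()
  for (occ in term_occurrences(doc)) {
    b <- occ$binding
    if (is.null(b)) next
    snap <- snaps[[b$snapshot]]
    if (is.null(snap) || !has_term(snap, occ$term_id)) next
    used <- union(used, b$snapshot)
    if (is.null(occ$term_label)) {
      doc <- doc_set(doc, c(occ$idx, "term_label"),
                     label_of(snap, occ$term_id))
    }
  }

  # 2. capture versions of exactly the snapshots whose terms occur
  versions <- lapply(snaps[sort(used)], function(s) s$version)
  doc <- doc_set(doc, c("doc_info", "ontology_versions"),
                 if (length(versions)) versions
                 else structure(list(), names = character()))

  # 3. summary fields (filled only when absent: submitted content is
  #    never altered)
  for (i in seq_along(doc$samples)) {
    s <- doc$samples[[i]]
    if (is.null(doc_get(s, c("sample_type", "summary")))) {
      doc <- doc_set(doc, list("samples", i, "sample_type", "summary"),
                     summarize_sample_type(s))
    }
  }
  for (i in seq_along(doc$experiments)) {
    e <- doc$experiments[[i]]
    if (is.null(doc_get(e, c("target", "summary")))) {
      doc <- doc_set(doc, list("experiments", i, "target", "summary"),
                     summarize_target(e, registries))
    }
  }

  # 4. provenance stamp: DOI preferred over version id
  src <- doc_get(doc, c("doc_info", "doi")) %||%
    doc_get(doc, c("doc_info", "version_id"))
  if (!is.null(src)) {
    doc <- doc_set(doc, c("doc_info", "augmented_from"), src)
  }
  doc
}

#' Summarize a sample's biospecimen description
#'
#' The `biospecimen_class` value selects which `sample_type` child carries
#' the defining description of the sample; the summary is that child's
#' human-readable label (cell line -> `cell_line`, cell type ->
#' `cell_type`, abnormal cell type -> `abnormal_cell_type`, organism part
#' -> `organism_part`).
#'
#' @param sample a sample object from a document.
#' @return The summary string.
#' @export
summarize_sample_type <- function(sample) {
  bios <- biospecimen_classes()
  bc <- sample$biospecimen_class
  if (!is.list(bc) || !is_string(bc$term_id)) {
    tm_error("biospecimen_child_missing", "sample has no biospecimen_class")
  }
  j <- match(bc$term_id, bios$term_id)
  if (is.na(j)) {
    tm_error("biospecimen_child_missing",
             sprintf("'%s' is not a recognised biospecimen class", bc$term_id))
  }
  child <- sample$sample_type[[bios$child[j]]]
  if (is.null(child)) {
    tm_error("biospecimen_child_missing",
             sprintf("biospecimen_class '%s' requires sample_type child '%s'",
                     bios$label[j], bios$child[j]))
  }
  child$term_label %||% child$term_id
}

# The technique rule table is data, not code: each row maps a technique
# class (an assay-ontology ancestor IRI) to a summary recipe.  Rows are
# tried in priority order; the catch-all row maps every other assay to the
# untargeted recipe.  Shipped as inst/extdata/technique_rules.tsv so
# adopters can extend it; rows beyond the gene-targeted immunoprecipitation
# rule are provisional.
technique_rules <- function() {
  path <- system.file("extdata", "technique_rules.tsv", package = "trackmeta")
  if (nzchar(path) && file.exists(path)) {
    utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  } else {
    default_technique_rules()
  }
}

default_technique_rules <- function() {
  data.frame(
    priority = c("1", "2", "3", "4"),
    ancestor_iri = c(onto_iri("TOA", 3), onto_iri("TOA", 15),
                     onto_iri("TOA", 13), onto_iri("TOA", 1)),
    recipe = c("gene", "feature", "phenotype", "none"),
    stringsAsFactors = FALSE)
}

#' Summarize an experiment's biological target
#'
#' The summary recipe is selected by classifying the experiment's
#' `technique` term against the technique rule table (first matching
#' ancestor wins): gene-targeted techniques yield the `gene_id` label
#' followed, after a single space, by `target_details` when non-empty;
#' feature-targeted techniques yield the `sequence_feature` label;
#' phenotype-targeted techniques the `phenotype` label; untargeted
#' techniques an empty string.
#'
#' @param experiment an experiment object from a document.
#' @param registries a `registry_set` (assay snapshot used for
#'   classification).
#' @return The summary string (possibly empty).
#' @export
summarize_target <- function(experiment, registries = default_registries()) {
  tech <- experiment$technique
  if (!is.list(tech) || !is_string(tech$term_id)) {
    tm_error("target_child_missing", "experiment has no technique term")
  }
  snap <- registries$ontologies[["toa"]]
  rules <- technique_rules()
  rules <- rules[order(as.integer(rules$priority)), , drop = FALSE]
  recipe <- NULL
  for (i in seq_len(nrow(rules))) {
    anc <- rules$ancestor_iri[i]
    hit <- tech$term_id == anc ||
      (has_term(snap, tech$term_id) && is_descendant(snap, tech$term_id, anc))
    if (hit) { recipe <- rules$recipe[i]; break }
  }
  if (is.null(recipe)) recipe <- "none"
  tgt <- experiment$target %||% list()
  need <- function(field, what) {
    v <- tgt[[field]]
    if (is.null(v)) {
      tm_error("target_child_missing",
               sprintf("technique recipe '%s' requires target child '%s'",
                       what, field))
    }
    v
  }
  switch(recipe,
    gene = {
      g <- need("gene_id", "gene")
      lab <- g$label %||% parse_curie(g$id)$accession
      det <- tgt$target_details
      if (is_string(det) && nzchar(det)) paste(lab, det) else lab
    },
    feature = {
      v <- need("sequence_feature", "feature")
      v$term_label %||% v$term_id
    },
    phenotype = {
      v <- need("phenotype", "phenotype")
      v$term_label %||% v$term_id
    },
    none = ""
  )
}
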