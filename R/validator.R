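# Full document validation: structural schema conformance plus the
# document-set rules that plain JSON Schema cannot express (uniqueness,
# foreign references, aggregation cycles, CURIE and ontology semantics,
# assembly-name consistency).  All problems accumulate into a deterministic
# report; nothing fails fast.

#' Validator rule kinds
#'
#' @return Character vector of every rule kind a report can contain.
#' @export
validation_rule_kinds <- function() {
  c("schema", "unique_violation", "foreign_ref", "curie_syntax",
    "curie_prefix", "curie_accession", "ontology_term", "ontology_ancestor",
    "ontology_label_mismatch", "assembly_name", "checksum_format",
    "doi_format", "cardinality", "aggregation_cycle",
    "biospecimen_child_missing")
}

issue <- function(rule_kind, idx, message) {
  list(rule_kind = rule_kind, path = path_str(idx), message = message)
}

new_report <- function(issues) {
  ord <- order(vapply(issues, `[[`, "", "path"),
               vapply(issues, `[[`, "", "rule_kind"),
               method = "radix")
  structure(list(issues = issues[ord], ok = length(issues) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("validation OK: 0 issues\n")
  } else {
    cat(sprintf("validation FAILED: %d issue(s)\n", length(x$issues)))
    for (i in x$issues) {
      cat(sprintf("  [%s] %s: %s\n", i$rule_kind, i$path, i$message))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(
    rule_kind = vapply(x$issues, `[[`, "", "rule_kind"),
    path = vapply(x$issues, `[[`, "", "path"),
    message = vapply(x$issues, `[[`, "", "message"),
    stringsAsFactors = FALSE)
}

#' Serialize a validation report to canonical JSON
#' @param report a `validation_report`.
#' @return JSON text.
#' @export
report_json <- function(report) {
  canonical_json(list(ok = report$ok,
                      issues = lapply(report$issues, function(i)
                        list(rule_kind = i$rule_kind, path = i$path,
                             message = i$message))))
}

# ---------------------------------------------------------------------------

#' Validate a metadata document
#'
#' Runs the structural schema check and all document-set rules against the
#' supplied registries.  Unknown extra fields never produce issues; absent
#' optional fields are never checked.  Ontology labels are optional
#' (augmentation-owned) but, when present, must match the snapshot label.
#'
#' @param doc a document.
#' @param registries a `registry_set`; defaults to the packaged fixture
#'   registries.
#' @return A `validation_report` with issues ordered by (path, rule_kind).
#' @export
validate_document <- function(doc, registries = default_registries()) {
  if (!inherits(registries, "registry_set")) {
    tm_error("configuration", "registries must be a registry_set")
  }
  issues <- c(
    check_structure(doc),
    check_unique_ids(doc),
    check_foreign_refs(doc),
    check_aggregation_acyclic(doc),
    check_curie_fields(doc, registries),
    check_ontology_fields(doc, registries$ontologies),
    check_assembly_fields(doc, registries),
    check_checksums(doc),
    check_doi(doc),
    check_cardinality(doc),
    check_biospecimen_children(doc)
  )
  new_report(issues)
}

# --- structural (schema) checks --------------------------------------------

check_structure <- function(doc) {
  spec <- model_spec()
  issues <- list()
  add <- function(i) issues[[length(issues) + 1L]] <<- i

  check_value <- function(desc, value, idx) {
    switch(desc$type,
      string = , doi = , checksum_value = {
        if (!is_string(value)) add(issue("schema", idx, "expected a string"))
        else if (!is.null(desc$enum) && !(value %in% desc$enum)) {
          add(issue("schema", idx,
                    sprintf("'%s' is not one of the allowed values", value)))
        }
      },
      url = {
        if (!is_string(value)) add(issue("schema", idx, "expected a string"))
        else if (!grepl("^(https?|ftp)://.+", value)) {
          add(issue("schema", idx,
                    sprintf("'%s' is not an http/https/ftp URL", value)))
        }
      },
      email = {
        if (!is_string(value)) add(issue("schema", idx, "expected a string"))
        else if (lengths(regmatches(value, gregexpr("@", value, fixed = TRUE))) != 1L) {
          add(issue("schema", idx,
                    sprintf("'%s' must contain exactly one '@'", value)))
        }
      },
      date = {
        if (!is_string(value) ||
            !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value) ||
            is.na(as.Date(value, format = "%Y-%m-%d"))) {
          add(issue("schema", idx, "expected an ISO8601 calendar date"))
        }
      },
      curie = , ref = {
        if (!is_string(value)) add(issue("schema", idx, "expected a string"))
      },
      map_string = {
        if (!is.list(value) || (length(value) && is.null(names(value)))) {
          add(issue("schema", idx, "expected an object of strings"))
        } else {
          for (k in names(value)) {
            if (!is_string(value[[k]])) {
              add(issue("schema", c(idx, k), "expected a string"))
            }
          }
        }
      },
      term_pair = {
        if (!is.list(value) || is.null(names(value))) {
          add(issue("schema", idx, "expected an ontology term object"))
        } else {
          tid <- value$term_id
          if (is.null(tid)) {
            add(issue("schema", idx, "missing required property 'term_id'"))
          } else if (!is_string(tid) || !nzchar(tid)) {
            add(issue("schema", c(idx, "term_id"), "term_id must be a non-empty string"))
          } else if (!is.null(desc$id_enum) && !(tid %in% desc$id_enum)) {
            add(issue("schema", c(idx, "term_id"),
                      sprintf("'%s' is not in the closed in-schema set", tid)))
          }
          if (!is.null(value$term_label) && !is_string(value$term_label)) {
            add(issue("schema", c(idx, "term_label"), "expected a string"))
          }
        }
      },
      object = {
        if (!is.list(value) || (length(value) > 0L && is.null(names(value)))) {
          add(issue("schema", idx, "expected an object"))
        } else {
          check_object(desc$fields, value, idx)
        }
      },
      array = {
        if (!is.list(value) || !is.null(names(value))) {
          add(issue("schema", idx, "expected an array"))
        } else {
          if (!is.null(desc$min_items) && length(value) < desc$min_items) {
            add(issue("schema", idx,
                      sprintf("expected at least %d item(s)", desc$min_items)))
          }
          for (i in seq_along(value)) {
            check_value(desc$item, value[[i]], c(idx, i))
          }
        }
      }
    )
  }

  check_object <- function(fields, value, idx) {
    for (fn in names(fields)) {
      d <- fields[[fn]]
      v <- value[[fn]]
      if (is.null(v)) {
        if (isTRUE(d$required) && !isTRUE(d$augmented)) {
          add(issue("schema", idx,
                    sprintf("missing required property '%s'", fn)))
        }
      } else {
        check_value(d, v, c(idx, fn))
      }
    }
  }

  if (is.null(doc$doc_info)) {
    add(issue("schema", list(), "missing required property 'doc_info'"))
  } else {
    check_value(f_obj(spec$doc_info, required = TRUE), doc$doc_info,
                list("doc_info"))
  }
  for (ln in names(doc_lists)) {
    lst <- doc[[ln]]
    if (is.null(lst)) {
      add(issue("schema", list(), sprintf("missing required property '%s'", ln)))
      next
    }
    if (!is.list(lst) || !is.null(names(lst))) {
      add(issue("schema", list(ln), "expected an array"))
      next
    }
    for (i in seq_along(lst)) {
      check_value(f_obj(spec[[doc_lists[[ln]]]], required = TRUE),
                  lst[[i]], list(ln, i))
    }
  }
  issues
}

# --- document-set checks ---------------------------------------------------

check_unique_ids <- function(doc) {
  issues <- list()
  for (ln in names(doc_lists)) {
    lst <- doc[[ln]]
    if (!is.list(lst) || !is.null(names(lst))) next
    ids <- vapply(lst, function(o) {
      v <- o$local_id
      if (is_string(v)) v else NA_character_
    }, character(1))
    dup <- ids[!is.na(ids) & duplicated(ids)]
    for (d in unique(dup)) {
      hits <- which(ids == d)
      for (i in hits[-1]) {
        issues[[length(issues) + 1L]] <-
          issue("unique_violation", list(ln, i, "local_id"),
                sprintf("local_id '%s' duplicates %s", d,
                        path_str(list(ln, hits[1], "local_id"))))
      }
    }
  }
  issues
}

# All (list_name, field, target_list) reference edges in the model.
ref_edges <- function() {
  spec <- model_spec()
  out <- list()
  for (ln in names(doc_lists)) {
    for (fn in names(spec[[doc_lists[[ln]]]])) {
      d <- spec[[doc_lists[[ln]]]][[fn]]
      if (d$type == "ref") {
        out[[length(out) + 1L]] <- list(list = ln, field = fn,
                                        target = d$target, multi = FALSE)
      } else if (d$type == "array" && d$item$type == "ref") {
        out[[length(out) + 1L]] <- list(list = ln, field = fn,
                                        target = d$item$target, multi = TRUE)
      }
    }
  }
  out
}

local_ids_of <- function(doc, ln) {
  lst <- doc[[ln]]
  if (!is.list(lst) || !is.null(names(lst))) return(character())
  ids <- vapply(lst, function(o) {
    v <- o$local_id
    if (is_string(v)) v else NA_character_
  }, character(1))
  ids[!is.na(ids)]
}

check_foreign_refs <- function(doc) {
  issues <- list()
  for (e in ref_edges()) {
    targets <- local_ids_of(doc, e$target)
    lst <- doc[[e$list]]
    if (!is.list(lst) || !is.null(names(lst))) next
    for (i in seq_along(lst)) {
      v <- lst[[i]][[e$field]]
      if (is.null(v)) next
      if (e$multi) {
        if (!is.list(v) || !is.null(names(v))) next
        for (j in seq_along(v)) {
          if (is_string(v[[j]]) && !(v[[j]] %in% targets)) {
            issues[[length(issues) + 1L]] <-
              issue("foreign_ref", list(e$list, i, e$field, j),
                    sprintf("'%s' does not name any %s local_id",
                            v[[j]], doc_lists[[e$target]]))
          }
        }
      } else if (is_string(v) && !(v %in% targets)) {
        issues[[length(issues) + 1L]] <-
          issue("foreign_ref", list(e$list, i, e$field),
                sprintf("'%s' does not name any %s local_id",
                        v, doc_lists[[e$target]]))
      }
    }
  }
  issues
}

#' Flag experiments on aggregation cycles
#'
#' An experiment may trace its provenance to upstream experiments through
#' `aggregated_from`; those links must form a DAG.  Every experiment lying
#' on a directed cycle is flagged.
#'
#' @param doc a document.
#' @return A list of issues (empty when acyclic).
#' @export
check_aggregation_acyclic <- function(doc) {
  exps <- doc$experiments
  if (!is.list(exps) || !is.null(names(exps))) return(list())
  ids <- vapply(exps, function(e) {
    v <- e$local_id
    if (is_string(v)) v else NA_character_
  }, character(1))
  adj <- lapply(exps, function(e) {
    af <- e$aggregated_from
    if (!is.list(af) || !is.null(names(af))) return(integer())
    tgt <- match(unlist(af, use.names = FALSE), ids)
    tgt[!is.na(tgt)]
  })
  n <- length(exps)
  on_cycle <- logical(n)
  for (v in seq_len(n)) {
    # reachable set from the successors of v; v is on a cycle iff v in it
    frontier <- adj[[v]]
    seen <- logical(n)
    while (length(frontier)) {
      u <- frontier[1]
      frontier <- frontier[-1]
      if (u == v) { on_cycle[v] <- TRUE; break }
      if (seen[u]) next
      seen[u] <- TRUE
      frontier <- c(frontier, adj[[u]])
    }
  }
  issues <- list()
  for (v in which(on_cycle)) {
    issues[[length(issues) + 1L]] <-
      issue("aggregation_cycle", list("experiments", v, "aggregated_from"),
            sprintf("experiment '%s' lies on an aggregated_from cycle", ids[v]))
  }
  issues
}

# --- CURIE fields ----------------------------------------------------------

# Enumerate every CURIE-typed occurrence with its allowed prefixes.
curie_occurrences <- function(doc) {
  spec <- model_spec()
  occs <- list()
  visit <- function(desc, value, idx) {
    if (is.null(value)) return()
    switch(desc$type,
      curie = {
        if (is_string(value)) {
          occs[[length(occs) + 1L]] <<-
            list(value = value, idx = idx, prefixes = desc$prefixes)
        }
      },
      object = {
        if (is.list(value) && !is.null(names(value)) || (is.list(value) && !length(value))) {
          for (fn in names(desc$fields)) {
            visit(desc$fields[[fn]], value[[fn]], c(idx, fn))
          }
        }
      },
      array = {
        if (is.list(value) && is.null(names(value))) {
          for (i in seq_along(value)) visit(desc$item, value[[i]], c(idx, i))
        }
      }
    )
  }
  visit(f_obj(spec$doc_info), doc$doc_info, list("doc_info"))
  for (ln in names(doc_lists)) {
    lst <- doc[[ln]]
    if (!is.list(lst) || !is.null(names(lst))) next
    for (i in seq_along(lst)) {
      visit(f_obj(spec[[doc_lists[[ln]]]]), lst[[i]], list(ln, i))
    }
  }
  occs
}

check_curie_fields <- function(doc, registries) {
  tab <- registries$curie
  issues <- list()
  for (occ in curie_occurrences(doc)) {
    parts <- tryCatch(parse_curie(occ$value), error = function(e) e)
    if (inherits(parts, "trackmeta_curie_syntax")) {
      issues[[length(issues) + 1L]] <-
        issue("curie_syntax", occ$idx, conditionMessage(parts))
      next
    }
    allowed <- occ$prefixes
    if (!identical(allowed, "*") && !(parts$prefix %in% allowed)) {
      issues[[length(issues) + 1L]] <-
        issue("curie_prefix", occ$idx,
              sprintf("prefix '%s' is not allowed here (expected %s)",
                      parts$prefix, paste(allowed, collapse = ", ")))
      next
    }
    row <- tab[tab$prefix == parts$prefix, , drop = FALSE]
    if (nrow(row) == 0L) {
      issues[[length(issues) + 1L]] <-
        issue("curie_prefix", occ$idx,
              sprintf("prefix '%s' is not registered", parts$prefix))
    } else if (!grepl(row$pattern[1], parts$accession, perl = TRUE)) {
      issues[[length(issues) + 1L]] <-
        issue("curie_accession", occ$idx,
              sprintf("accession '%s' does not match the '%s' pattern",
                      parts$accession, parts$prefix))
    }
  }
  issues
}

# --- ontology fields -------------------------------------------------------

# Enumerate every ontology-term occurrence together with its snapshot
# binding.  Shared by the validator and the augmenter.
term_occurrences <- function(doc) {
  spec <- model_spec()
  occs <- list()
  visit <- function(desc, value, idx) {
    if (is.null(value)) return()
    switch(desc$type,
      term_pair = {
        if (is.list(value) && !is.null(names(value)) && is_string(value$term_id)) {
          occs[[length(occs) + 1L]] <<-
            list(term_id = value$term_id, term_label = value$term_label,
                 idx = idx, binding = desc$binding)
        }
      },
      object = {
        if (is.list(value)) {
          for (fn in names(desc$fields)) {
            visit(desc$fields[[fn]], value[[fn]], c(idx, fn))
          }
        }
      },
      array = {
        if (is.list(value) && is.null(names(value))) {
          for (i in seq_along(value)) visit(desc$item, value[[i]], c(idx, i))
        }
      }
    )
  }
  for (ln in names(doc_lists)) {
    lst <- doc[[ln]]
    if (!is.list(lst) || !is.null(names(lst))) next
    for (i in seq_along(lst)) {
      visit(f_obj(spec[[doc_lists[[ln]]]]), lst[[i]], list(ln, i))
    }
  }
  occs
}

#' Check ontology-constrained fields
#'
#' For each ontology-bound field: the term must exist in its assigned
#' snapshot, descend from every required ancestor, and (when a label is
#' present) carry exactly the snapshot label.
#'
#' @param doc a document.
#' @param snapshots named list of `ontology_snapshot` objects.
#' @return A list of issues.
#' @export
check_ontology_fields <- function(doc, snapshots) {
  issues <- list()
  for (occ in term_occurrences(doc)) {
    b <- occ$binding
    if (is.null(b)) next
    snap <- snapshots[[b$snapshot]]
    if (is.null(snap)) {
      tm_error("configuration",
               sprintf("no snapshot named '%s' in the registry", b$snapshot))
    }
    if (!has_term(snap, occ$term_id)) {
      issues[[length(issues) + 1L]] <-
        issue("ontology_term", c(occ$idx, "term_id"),
              sprintf("term '%s' not found in ontology '%s' (version %s)",
                      occ$term_id, snap$name, snap$version))
      next
    }
    for (anc in b$ancestors) {
      if (occ$term_id != anc && !is_descendant(snap, occ$term_id, anc)) {
        issues[[length(issues) + 1L]] <-
          issue("ontology_ancestor", c(occ$idx, "term_id"),
                sprintf("term '%s' does not descend from required ancestor '%s'",
                        occ$term_id, anc))
      }
    }
    if (!is.null(occ$term_label) && is_string(occ$term_label)) {
      expected <- label_of(snap, occ$term_id)
      if (occ$term_label != expected) {
        issues[[length(issues) + 1L]] <-
          issue("ontology_label_mismatch", c(occ$idx, "term_label"),
                sprintf("label '%s' does not match snapshot label '%s'",
                        occ$term_label, expected))
      }
    }
  }
  issues
}

# --- assembly, checksum, DOI, cardinality, biospecimen ---------------------

check_assembly_fields <- function(doc, registries) {
  tab <- registries$assemblies
  issues <- list()
  lst <- doc$tracks
  if (!is.list(lst) || !is.null(names(lst))) return(issues)
  for (i in seq_along(lst)) {
    tr <- lst[[i]]
    aid <- tr$assembly_id
    an <- tr$annotation_name
    if (!is_string(aid) || !is_string(an)) next
    entry <- tab[tab$curie == aid, , drop = FALSE]
    if (nrow(entry) == 0L) {
      issues[[length(issues) + 1L]] <-
        issue("assembly_name", list("tracks", i, "assembly_id"),
              sprintf("assembly accession '%s' is not in the assembly registry", aid))
      next
    }
    if (!(an %in% entry$name)) {
      issues[[length(issues) + 1L]] <-
        issue("assembly_name", list("tracks", i, "annotation_name"),
              sprintf("'%s' is not the canonical name or a registered synonym of %s",
                      an, entry$canonical[1]))
    }
  }
  issues
}

check_checksums <- function(doc) {
  issues <- list()
  lst <- doc$tracks
  if (!is.list(lst) || !is.null(names(lst))) return(issues)
  for (i in seq_along(lst)) {
    cs <- lst[[i]]$checksum
    if (!is.list(cs)) next
    m <- cs$method
    v <- cs$value
    if (!is_string(m) || !is_string(v)) next
    if (!(m %in% names(checksum_lengths))) next  # schema enum handles it
    if (!grepl("^[0-9a-f]+$", v) || nchar(v) != checksum_lengths[[m]]) {
      issues[[length(issues) + 1L]] <-
        issue("checksum_format", list("tracks", i, "checksum", "value"),
              sprintf("%s digest must be %d lowercase hex characters",
                      m, checksum_lengths[[m]]))
    }
  }
  issues
}

check_doi <- function(doc) {
  issues <- list()
  for (fld in c("doi", "derived_from", "augmented_from")) {
    v <- doc_get(doc, c("doc_info", fld))
    if (fld != "doi" && !is.null(v)) next  # free identifier strings
    if (is_string(v) && !validate_doi(v)) {
      issues[[length(issues) + 1L]] <-
        issue("doi_format", list("doc_info", fld),
              sprintf("'%s' is not a valid DOI", v))
    }
  }
  issues
}

check_cardinality <- function(doc) {
  issues <- list()
  lst <- doc$experiments
  if (!is.list(lst) || !is.null(names(lst))) return(issues)
  for (i in seq_along(lst)) {
    e <- lst[[i]]
    has_sample <- is_string(e$sample_ref) && nzchar(e$sample_ref)
    af <- e$aggregated_from
    has_agg <- is.list(af) && is.null(names(af)) && length(af) > 0L
    if (has_sample == has_agg) {
      issues[[length(issues) + 1L]] <-
        issue("cardinality", list("experiments", i),
              "exactly one of sample_ref / aggregated_from must be set")
    }
    if (has_agg) {
      vals <- unlist(af, use.names = FALSE)
      if (anyDuplicated(vals)) {
        issues[[length(issues) + 1L]] <-
          issue("cardinality", list("experiments", i, "aggregated_from"),
                "aggregated_from contains duplicate experiment ids")
      }
    }
  }
  issues
}

check_biospecimen_children <- function(doc) {
  bios <- biospecimen_classes()
  issues <- list()
  lst <- doc$samples
  if (!is.list(lst) || !is.null(names(lst))) return(issues)
  for (i in seq_along(lst)) {
    s <- lst[[i]]
    bc <- s$biospecimen_class
    if (!is.list(bc) || !is_string(bc$term_id)) next
    j <- match(bc$term_id, bios$term_id)
    if (is.na(j)) next  # schema enum handles it
    child <- bios$child[j]
    st <- s$sample_type
    if (!is.list(st) || is.null(st[[child]])) {
      issues[[length(issues) + 1L]] <-
        issue("biospecimen_child_missing", list("samples", i, "sample_type"),
              sprintf("biospecimen_class '%s' requires sample_type child '%s'",
                      bios$label[j], child))
    }
  }
  issues
}
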