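# Offline registry stand-ins: CURIE prefix table, DOI syntax, genome
# assembly synonym table, and versioned ontology snapshots.  Real services
# (Identifiers.org, assembly reports, ontology lookup) can be swapped in by
# supplying a registry directory with the same tabular layout.

# ---------------------------------------------------------------------------
# CURIEs

#' Parse a compact identifier (CURIE)
#'
#' Splits a `prefix:accession` compact identifier at the first colon.
#'
#' @param s a single character string.
#' @return A list with elements `prefix` and `accession`.
#' @examples
#' parse_curie("insdc.gca:GCF_000001405.13")
#' @export
parse_curie <- function(s) {
  if (!is_string(s)) tm_error("curie_syntax", "CURIE must be a single string")
  pos <- regexpr(":", s, fixed = TRUE)
  if (pos < 0L) {
    tm_error("curie_syntax", sprintf("'%s' has no colon separator", s))
  }
  prefix <- substr(s, 1L, pos - 1L)
  accession <- substr(s, pos + 1L, nchar(s))
  if (!nzchar(prefix)) tm_error("curie_syntax", sprintf("'%s' has an empty prefix", s))
  if (!nzchar(accession)) tm_error("curie_syntax", sprintf("'%s' has an empty accession", s))
  list(prefix = prefix, accession = accession)
}

#' Resolve a CURIE to a URL through a prefix registry
#'
#' @param curie a `prefix:accession` string.
#' @param registry a registry set (see [make_fixture_registries()]) or its
#'   `curie` table.
#' @return The resolved URL string.
#' @examples
#' reg <- make_fixture_registries()
#' resolve_curie("insdc.gca:GCF_000001405.13", reg)
#' @export
resolve_curie <- function(curie, registry) {
  tab <- curie_table(registry)
  parts <- parse_curie(curie)
  row <- tab[tab$prefix == parts$prefix, , drop = FALSE]
  if (nrow(row) == 0L) {
    tm_error("curie_prefix", sprintf("unknown CURIE prefix '%s'", parts$prefix))
  }
  if (!grepl(row$pattern[1], parts$accession, perl = TRUE)) {
    tm_error("curie_accession",
             sprintf("accession '%s' does not match pattern '%s' for prefix '%s'",
                     parts$accession, row$pattern[1], parts$prefix))
  }
  sub("{accession}", parts$accession, row$url_template[1], fixed = TRUE)
}

curie_table <- function(registry) {
  if (is.data.frame(registry)) return(registry)
  if (inherits(registry, "registry_set")) return(registry$curie)
  tm_error("configuration", "expected a registry set or CURIE table")
}

#' Validate DOI syntax
#'
#' Accepts `10.<registrant>/<suffix>` with a digits-only registrant code.
#' An optional leading `doi:` scheme and surrounding whitespace are
#' stripped before matching.
#'
#' @param s a single character string.
#' @return `TRUE` or `FALSE`.
#' @examples
#' validate_doi("10.1234/abc.v2")
#' validate_doi("doi:10.1234/abc")
#' validate_doi("11.1234/abc")
#' @export
validate_doi <- function(s) {
  if (!is_string(s)) return(FALSE)
  s <- trimws(s)
  s <- sub("^doi:", "", s)
  grepl("^10\\.[0-9]+/.+$", s)
}

# ---------------------------------------------------------------------------
# Genome assemblies

#' Normalize a genome assembly name
#'
#' Maps a canonical reference-consortium assembly name or one of its
#' registered synonyms to the canonical name plus the chromosome naming
#' scheme the queried name implies ("grc" or "ucsc").
#'
#' @param name assembly name, e.g. `"GRCh37"` or `"hg19"`.
#' @param registry a registry set or its `assemblies` table.
#' @return A list with `canonical_name`, `naming_scheme` and `assembly_curie`.
#' @examples
#' reg <- make_fixture_registries()
#' normalize_assembly("hg19", reg)
#' @export
normalize_assembly <- function(name, registry) {
  tab <- assembly_table(registry)
  if (!is_string(name)) tm_error("unknown_assembly", "assembly name must be a string")
  hit <- tab[tab$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    tm_error("unknown_assembly", sprintf("unknown assembly name '%s'", name))
  }
  list(canonical_name = hit$canonical[1],
       naming_scheme = hit$scheme[1],
       assembly_curie = hit$curie[1])
}

assembly_table <- function(registry) {
  if (is.data.frame(registry)) return(registry)
  if (inherits(registry, "registry_set")) return(registry$assemblies)
  tm_error("configuration", "expected a registry set or assembly table")
}

# Long-format assembly table constructor: one row per known name (canonical
# names carry scheme "grc"); checks registry-wide synonym uniqueness.
new_assembly_table <- function(canonical, synonyms, schemes, curies) {
  rows <- list()
  for (i in seq_along(canonical)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = canonical[i], canonical = canonical[i], scheme = "grc",
      curie = curies[i], stringsAsFactors = FALSE)
    syns <- synonyms[[i]]
    schs <- schemes[[i]]
    for (j in seq_along(syns)) {
      if (syns[j] %in% canonical) {
        tm_error("configuration",
                 sprintf("synonym '%s' collides with a canonical name", syns[j]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = syns[j], canonical = canonical[i], scheme = schs[j],
        curie = curies[i], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$name)) {
    tm_error("configuration", "assembly names/synonyms are not unique")
  }
  tab
}

# ---------------------------------------------------------------------------
# Ontology snapshots

#' Construct an ontology snapshot
#'
#' A snapshot is a named, versioned set of terms forming a DAG over
#' `parent` links.  Multiple parents are allowed; cycles are rejected.
#'
#' @param name short ontology name.
#' @param version version string captured into augmented documents.
#' @param terms data frame with columns `iri`, `label`, `parents`
#'   (pipe-separated parent IRIs, empty for roots).
#' @return An object of class `ontology_snapshot`.
#' @export
new_ontology_snapshot <- function(name, version, terms) {
  stopifnot(is.data.frame(terms),
            all(c("iri", "label", "parents") %in% names(terms)))
  if (anyDuplicated(terms$iri)) {
    tm_error("configuration", sprintf("ontology '%s': duplicate term IRIs", name))
  }
  parents <- lapply(strsplit(terms$parents, "|", fixed = TRUE),
                    function(p) p[nzchar(p)])
  names(parents) <- terms$iri
  unknown <- setdiff(unlist(parents), terms$iri)
  if (length(unknown)) {
    tm_error("configuration",
             sprintf("ontology '%s': unknown parent IRIs: %s",
                     name, paste(unknown, collapse = ", ")))
  }
  snap <- structure(
    list(name = name, version = version, terms = terms, parents = parents),
    class = "ontology_snapshot")
  detect_ontology_cycle(snap)
  snap
}

detect_ontology_cycle <- function(snapshot) {
  # iterative colouring DFS over parent links
  state <- new.env(parent = emptyenv())
  visit <- function(iri, stack) {
    if (iri %in% stack) {
      tm_error("ontology_cycle",
               sprintf("ontology '%s': cycle through term %s",
                       snapshot$name, iri))
    }
    if (!is.null(state[[iri]])) return(invisible())
    for (p in snapshot$parents[[iri]]) visit(p, c(stack, iri))
    state[[iri]] <- TRUE
    invisible()
  }
  for (iri in snapshot$terms$iri) visit(iri, character())
  invisible(snapshot)
}

#' Look up the label of an ontology term
#'
#' @param snapshot an `ontology_snapshot`.
#' @param iri term IRI.
#' @return The stored human-readable label.
#' @export
label_of <- function(snapshot, iri) {
  i <- match(iri, snapshot$terms$iri)
  if (is.na(i)) {
    tm_error("ontology_term",
             sprintf("term '%s' not found in ontology '%s' (version %s)",
                     iri, snapshot$name, snapshot$version))
  }
  snapshot$terms$label[i]
}

has_term <- function(snapshot, iri) {
  iri %in% snapshot$terms$iri
}

#' Test ontology descendance
#'
#' `TRUE` iff `iri` is a proper descendant of `ancestor_iri` via one or
#' more parent links (a term is not its own descendant).
#'
#' @param snapshot an `ontology_snapshot`.
#' @param iri term IRI (must exist in the snapshot).
#' @param ancestor_iri candidate ancestor IRI.
#' @return `TRUE` or `FALSE`.
#' @export
is_descendant <- function(snapshot, iri, ancestor_iri) {
  if (!has_term(snapshot, iri)) {
    tm_error("ontology_term",
             sprintf("term '%s' not found in ontology '%s'", iri, snapshot$name))
  }
  frontier <- snapshot$parents[[iri]]
  seen <- character()
  while (length(frontier)) {
    nxt <- frontier[1]
    frontier <- frontier[-1]
    if (nxt == ancestor_iri) return(TRUE)
    if (nxt %in% seen) next
    seen <- c(seen, nxt)
    frontier <- c(frontier, snapshot$parents[[nxt]])
  }
  FALSE
}

# ---------------------------------------------------------------------------
# Tabular serialization (External interface layout)
#
# curie_registry.tsv: prefix <TAB> pattern <TAB> url_template
# assemblies.tsv:     name <TAB> canonical <TAB> scheme <TAB> curie
# ontology_<name>.tsv: first line "# ontology=<name> version=<version>",
#                      then header iri/label/parents; parents pipe-separated.

#' Load an ontology snapshot from its TSV serialization
#'
#' @param path path to an `ontology_*.tsv` file.
#' @return An `ontology_snapshot`.
#' @export
load_ontology_snapshot <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L || !grepl("^# ontology=", lines[1])) {
    tm_error("configuration",
             sprintf("'%s' is not an ontology snapshot file", path))
  }
  m <- regmatches(lines[1],
                  regexec("^# ontology=(\\S+) version=(\\S+)$", lines[1]))[[1]]
  if (length(m) != 3L) {
    tm_error("configuration", sprintf("malformed snapshot header in '%s'", path))
  }
  terms <- utils::read.delim(text = lines[-1], colClasses = "character",
                             stringsAsFactors = FALSE)
  if (is.null(terms$parents)) terms$parents <- ""
  terms$parents[is.na(terms$parents)] <- ""
  new_ontology_snapshot(m[2], m[3], terms)
}

write_ontology_snapshot <- function(snapshot, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# ontology=%s version=%s", snapshot$name, snapshot$version), con)
  utils::write.table(snapshot$terms[, c("iri", "label", "parents")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a registry set from a directory
#'
#' The directory must contain `curie_registry.tsv`, `assemblies.tsv` and
#' one or more `ontology_*.tsv` snapshot files.
#'
#' @param dir directory path.
#' @return A `registry_set`.
#' @export
load_registries <- function(dir) {
  cpath <- file.path(dir, "curie_registry.tsv")
  apath <- file.path(dir, "assemblies.tsv")
  opaths <- list.files(dir, pattern = "^ontology_.*\\.tsv$", full.names = TRUE)
  if (!file.exists(cpath) || !file.exists(apath) || length(opaths) == 0L) {
    tm_error("configuration",
             sprintf("registry directory '%s' is missing required tables", dir))
  }
  curie <- utils::read.delim(cpath, colClasses = "character",
                             stringsAsFactors = FALSE)
  assemblies <- utils::read.delim(apath, colClasses = "character",
                                  stringsAsFactors = FALSE)
  snaps <- lapply(sort(opaths), load_ontology_snapshot)
  names(snaps) <- vapply(snaps, function(s) s$name, character(1))
  new_registry_set(curie, assemblies, snaps)
}

#' Write a registry set to a directory
#'
#' @param registries a `registry_set`.
#' @param dir target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_registries <- function(registries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(registries$curie, file.path(dir, "curie_registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(registries$assemblies, file.path(dir, "assemblies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (snap in registries$ontologies) {
    write_ontology_snapshot(snap, file.path(dir, paste0("ontology_", snap$name, ".tsv")))
  }
  invisible(dir)
}

new_registry_set <- function(curie, assemblies, ontologies) {
  stopifnot(all(c("prefix", "pattern", "url_template") %in% names(curie)))
  if (any(grepl(":", curie$prefix, fixed = TRUE)) ||
      any(curie$prefix != tolower(curie$prefix))) {
    tm_error("configuration", "CURIE prefixes must be lowercase and colon-free")
  }
  for (p in curie$pattern) {
    ok <- tryCatch({ grepl(p, "x", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) tm_error("configuration", sprintf("CURIE pattern '%s' does not compile", p))
  }
  structure(list(curie = curie, assemblies = assemblies,
                 ontologies = ontologies),
            class = "registry_set")
}

#' @export
print.registry_set <- function(x, ...) {
  cat(sprintf("<registry_set: %d CURIE prefixes, %d assembly names, %d ontologies (%s)>\n",
              nrow(x$curie), nrow(x$assemblies), length(x$ontologies),
              paste(vapply(x$ontologies,
                           function(s) paste0(s$name, "@", s$version),
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' @export
print.ontology_snapshot <- function(x, ...) {
  cat(sprintf("<ontology_snapshot '%s' version %s: %d terms>\n",
              x$name, x$version, nrow(x$terms)))
  invisible(x)
}
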