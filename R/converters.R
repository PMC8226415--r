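# Format bridges.
#
# GSuite dialect (tabular track collection): optional '#' comment preamble,
# one header line starting "###" with tab-separated column names (first
# column "uri"), tab-separated data rows, "." for a missing value.
#
# Track hubs: UCSC-style hub.txt / genomes.txt / trackDb.txt stanza files
# (blank-line-separated key/value blocks, child tracks indented, keys being
# the first whitespace-delimited token).

gsuite_columns <- c("uri", "title", "genome", "file_format", "track_type",
                    "condensed_data_type", "technique", "target_summary",
                    "sample_summary", "study_name", "source_collection")

new_gsuite_table <- function(columns, rows, preamble = character()) {
  if (anyDuplicated(columns)) tm_error("gsuite_format", "duplicate column names")
  if (columns[1] != "uri") tm_error("gsuite_format", "first column must be 'uri'")
  for (r in rows) stopifnot(length(r) == length(columns))
  structure(list(preamble = preamble, columns = columns, rows = rows),
            class = "gsuite_table")
}

#' @export
print.gsuite_table <- function(x, ...) {
  cat(sprintf("<gsuite_table: %d columns, %d rows>\n",
              length(x$columns), length(x$rows)))
  invisible(x)
}

#' Export a document to a tabular track collection (GSuite dialect)
#'
#' One row per track; summary and label columns fall back to the missing
#' value "." when the document has not been augmented.
#'
#' @param doc a document (augmented or not).
#' @return A `gsuite_table`; serialize with [format_gsuite()].
#' @export
to_gsuite <- function(doc) {
  by_id <- function(lst) {
    ids <- vapply(lst, function(o) o$local_id %||% NA_character_, character(1))
    stats::setNames(lst, ids)
  }
  colls <- by_id(doc$collections %||% list())
  studies <- by_id(doc$studies %||% list())
  samples <- by_id(doc$samples %||% list())
  exps <- by_id(doc$experiments %||% list())
  cell <- function(v) if (is_string(v) && nzchar(v)) v else NA_character_
  rows <- lapply(doc$tracks %||% list(), function(tr) {
    e <- exps[[tr$experiment_ref %||% ""]]
    st <- if (!is.null(e)) studies[[e$study_ref %||% ""]]
    sm <- if (!is.null(e)) samples[[e$sample_ref %||% ""]]
    co <- colls[[tr$source_coll_ref %||% ""]]
    c(uri = cell(tr$file_url),
      title = cell(tr$label_short),
      genome = cell(tr$annotation_name),
      file_format = cell(doc_get(tr, c("file_format", "term_label"))),
      track_type = cell(tr$genomic_track_type),
      condensed_data_type = cell(tr$type_of_condensed_data),
      technique = cell(doc_get(e, c("technique", "term_label"))),
      target_summary = cell(doc_get(e, c("target", "summary"))),
      sample_summary = cell(doc_get(sm, c("sample_type", "summary"))),
      study_name = cell(doc_get(st, "name")),
      source_collection = cell(doc_get(co, "name")))
  })
  new_gsuite_table(gsuite_columns, lapply(rows, unname))
}

#' Serialize a `gsuite_table` to text
#' @param table a `gsuite_table`.
#' @return A single string (newline-terminated).
#' @export
format_gsuite <- function(table) {
  lines <- c(table$preamble,
             paste0("###", paste(table$columns, collapse = "\t")),
             vapply(table$rows, function(r) {
               r[is.na(r)] <- "."
               paste(r, collapse = "\t")
             }, character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse GSuite text into a `gsuite_table`
#'
#' @param text GSuite text (string or character vector of lines).
#' @return A `gsuite_table`; cells holding "." become `NA`.
#' @export
parse_gsuite <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  i <- 1L
  preamble <- character()
  while (i <= length(lines) && grepl("^#", lines[i]) &&
         !grepl("^###", lines[i])) {
    preamble <- c(preamble, lines[i])
    i <- i + 1L
  }
  if (i > length(lines) || !grepl("^###", lines[i])) {
    tm_error("gsuite_format",
             sprintf("line %d: expected a '###' header line", i))
  }
  columns <- strsplit(sub("^###", "", lines[i]), "\t", fixed = TRUE)[[1]]
  if (length(columns) == 0L || columns[1] != "uri") {
    tm_error("gsuite_format",
             sprintf("line %d: first column must be 'uri'", i))
  }
  rows <- list()
  for (j in seq.int(i + 1L, length.out = max(0L, length(lines) - i))) {
    if (!nzchar(lines[j])) next
    fields <- strsplit(lines[j], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(columns)) {
      tm_error("gsuite_format",
               sprintf("line %d: expected %d fields, found %d",
                       j, length(columns), length(fields)))
    }
    fields[fields == "."] <- NA_character_
    rows[[length(rows) + 1L]] <- fields
  }
  new_gsuite_table(columns, rows, preamble)
}

# Map GSuite/trackDb format labels back to assay-snapshot format terms.
format_label_to_term <- function(label, registries) {
  snap <- registries$ontologies[["toa"]]
  hit <- snap$terms$iri[snap$terms$label == label]
  if (length(hit) == 1L &&
      is_descendant(snap, hit, onto_iri("TOA", 100))) {
    list(term_id = hit, term_label = label)
  } else {
    NULL
  }
}

#' Reconstruct a partial document from GSuite text
#'
#' Recovers track records (URI, labels, assembly name, vocabulary fields)
#' and a single synthetic collection; other object types are stubs.  The
#' result is a draft: it is not expected to pass validation until curated.
#'
#' @param text GSuite text.
#' @param registries registry set used to map format labels back to terms.
#' @return A `track_doc`.
#' @export
from_gsuite <- function(text, registries = default_registries()) {
  gt <- parse_gsuite(text)
  col <- function(r, name) {
    j <- match(name, gt$columns)
    if (is.na(j)) NA_character_ else r[j]
  }
  tracks <- list()
  for (k in seq_along(gt$rows)) {
    r <- gt$rows[[k]]
    tr <- list(local_id = sprintf("track_%d", k),
               source_coll_ref = "gsuite_import")
    put <- function(tr, field, value) {
      if (!is.na(value)) tr[[field]] <- value
      tr
    }
    tr <- put(tr, "file_url", col(r, "uri"))
    tr <- put(tr, "label_short", col(r, "title"))
    tr <- put(tr, "annotation_name", col(r, "genome"))
    tr <- put(tr, "genomic_track_type", col(r, "track_type"))
    tr <- put(tr, "type_of_condensed_data", col(r, "condensed_data_type"))
    ff <- col(r, "file_format")
    if (!is.na(ff)) {
      tr$file_format <- format_label_to_term(ff, registries) %||%
        list(term_label = ff)
    }
    tracks[[k]] <- tr
  }
  structure(list(
    doc_info = list(local_id = "gsuite_import_draft"),
    collections = list(list(local_id = "gsuite_import",
                            name = "GSuite import")),
    studies = list(),
    samples = list(),
    experiments = list(),
    tracks = tracks), class = "track_doc")
}

# ---------------------------------------------------------------------------
# Track hub import

# Parse blank-line-separated key/value stanzas; indentation is flattened,
# '#' comment lines are dropped, the key is the first whitespace token.
parse_hub_stanzas <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  stanzas <- list()
  current <- list()
  flush <- function() {
    if (length(current)) stanzas[[length(stanzas) + 1L]] <<- current
    current <<- list()
  }
  for (raw in lines) {
    line <- trimws(raw)
    if (!nzchar(line)) { flush(); next }
    if (grepl("^#", line)) next
    m <- regexpr("\\s", line)
    if (m < 0L) {
      key <- line; value <- ""
    } else {
      key <- substr(line, 1L, m - 1L)
      value <- trimws(substr(line, m + 1L, nchar(line)))
    }
    if (key %in% names(current)) {
      tm_error("hub_format",
               sprintf("duplicate key '%s' within one stanza", key))
    }
    current[[key]] <- value
  }
  flush()
  stanzas
}

trackdb_format_map <- c(bigWig = "BigWig", bigBed = "BigBed", bcf = "BCF",
                        bed = "BED", bedGraph = "bedGraph")

#' Import UCSC-style track hub metadata as a draft document
#'
#' The hub stanza becomes a track collection; every leaf trackDb stanza
#' carrying a `bigDataUrl` becomes a track (`file_url` from bigDataUrl,
#' `label_short`/`label_long` from shortLabel/longLabel, `file_format`
#' from the first token of `type`, `annotation_name` from the genome).
#' Key=value pairs on a `metadata` line are retained as unknown extra
#' fields.  Fields the hub cannot supply are left absent and enumerated in
#' the import log: the draft is expected to FAIL validation until curated.
#'
#' @param hub_text contents of hub.txt.
#' @param genomes_text contents of genomes.txt.
#' @param trackdb_texts named list/vector of trackDb.txt contents, one per
#'   genome (a single unnamed text is accepted when there is one genome).
#' @param registries registry set for assembly-name normalization.
#' @return A list with `document` (a `track_doc`) and `log` (character
#'   vector of import notes), class `hub_import`.
#' @export
import_trackhub <- function(hub_text, genomes_text, trackdb_texts,
                            registries = default_registries()) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  hub <- parse_hub_stanzas(hub_text)
  if (length(hub) == 0L || is.null(hub[[1]]$hub)) {
    tm_error("hub_format", "hub.txt does not start with a 'hub' stanza")
  }
  hub <- hub[[1]]

  genome_stanzas <- Filter(function(s) !is.null(s$genome),
                           parse_hub_stanzas(genomes_text))
  if (length(genome_stanzas) == 0L) {
    tm_error("hub_format", "genomes.txt contains no 'genome' stanza")
  }

  if (is.null(names(trackdb_texts))) {
    if (length(trackdb_texts) == 1L && length(genome_stanzas) == 1L) {
      names(trackdb_texts) <- genome_stanzas[[1]]$genome
    } else {
      tm_error("hub_format", "trackdb_texts must be named by genome")
    }
  }

  coll_id <- hub$hub
  collection <- list(local_id = coll_id)
  if (!is.null(hub$shortLabel)) collection$name <- hub$shortLabel
  if (!is.null(hub$longLabel)) collection$description <- hub$longLabel
  contact <- list(name = coll_id)
  if (!is.null(hub$email)) contact$email <- hub$email
  else note("hub.txt has no contact email")
  collection$contact <- contact
  note("collection '%s': source_url not present in a track hub", coll_id)

  tracks <- list()
  for (gs in genome_stanzas) {
    genome <- gs$genome
    tdb_text <- trackdb_texts[[genome]]
    if (is.null(tdb_text)) {
      note("genome '%s': no trackDb text supplied, skipped", genome)
      next
    }
    annotation <- genome
    assembly_curie <- NULL
    norm <- tryCatch(normalize_assembly(genome, registries),
                     error = function(e) NULL)
    if (is.null(norm)) {
      note("genome '%s' is not in the assembly registry; kept verbatim", genome)
    } else {
      assembly_curie <- norm$assembly_curie
    }
    stanzas <- Filter(function(s) !is.null(s$track),
                      parse_hub_stanzas(tdb_text))
    parents <- unique(vapply(stanzas, function(s) {
      p <- s$parent
      if (is.null(p)) NA_character_ else strsplit(p, "\\s+")[[1]][1]
    }, character(1)))
    parents <- parents[!is.na(parents)]
    for (s in stanzas) {
      name <- s$track
      if (name %in% parents) {
        note("stanza '%s' is a container, no track emitted", name)
        next
      }
      if (is.null(s$bigDataUrl)) {
        note("leaf stanza '%s' has no bigDataUrl, no track emitted", name)
        next
      }
      tr <- list(local_id = name, source_coll_ref = coll_id,
                 experiment_ref = "experiment_stub",
                 file_url = s$bigDataUrl,
                 annotation_name = annotation)
      if (!is.null(assembly_curie)) tr$assembly_id <- assembly_curie
      if (!is.null(s$shortLabel)) tr$label_short <- s$shortLabel
      if (!is.null(s$longLabel)) tr$label_long <- s$longLabel
      if (!is.null(s$type)) {
        token <- strsplit(s$type, "\\s+")[[1]][1]
        mapped <- unname(trackdb_format_map[token])
        if (!is.na(mapped)) {
          tr$file_format <- format_label_to_term(mapped, registries) %||%
            list(term_label = mapped)
        } else {
          tr$file_format <- list(term_label = token)
          note("track '%s': unmapped trackDb type '%s' kept as plain label",
               name, token)
        }
      }
      if (!is.null(s$metadata)) {
        for (tok in strsplit(s$metadata, "\\s+")[[1]]) {
          eq <- regexpr("=", tok, fixed = TRUE)
          if (eq > 1L && eq < nchar(tok)) {
            tr[[substr(tok, 1L, eq - 1L)]] <- substr(tok, eq + 1L, nchar(tok))
          }
        }
      }
      note("track '%s': description, raw_file_ids, vocabulary fields and checksum need curation", name)
      tracks[[length(tracks) + 1L]] <- tr
    }
  }

  doc <- structure(list(
    doc_info = list(local_id = paste0(coll_id, "_draft")),
    collections = list(collection),
    studies = list(list(local_id = "study_stub", collection_ref = coll_id)),
    samples = list(list(local_id = "sample_stub")),
    experiments = list(list(local_id = "experiment_stub",
                            study_ref = "study_stub",
                            sample_ref = "sample_stub")),
    tracks = tracks), class = "track_doc")
  note("doc_info, study, sample and experiment stubs need curation")
  structure(list(document = doc, log = log), class = "hub_import")
}

#' @export
print.hub_import <- function(x, ...) {
  cat(sprintf("<hub_import: %d track(s), %d log line(s)>\n",
              length(x$document$tracks), length(x$log)))
  invisible(x)
}
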