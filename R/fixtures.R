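# Deterministic fixture generators: the package's entire test input supply.
# Registries are offline stand-ins (reserved "onto.invalid" IRI base and
# example.org URL templates so fixture terms can never collide with real
# ontologies or resolvers).  Documents are generated from a single integer
# seed; every piece of randomness flows from it.

# --- fixture ontologies ----------------------------------------------------

ont_rows <- function(ns, entries) {
  data.frame(
    iri = vapply(entries, function(e) onto_iri(ns, e[[1]]), character(1)),
    label = vapply(entries, function(e) e[[2]], character(1)),
    parents = vapply(entries, function(e) {
      ps <- e[[3]]
      if (length(ps) == 0L) "" else
        paste(vapply(ps, function(p) onto_iri(ns, p), character(1)),
              collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE)
}

fixture_toa <- function() {
  # assay stand-in ontology: assays, data formats, biological target
  # entities (three roots, >= 3 levels)
  new_ontology_snapshot("toa", "2021-03-12", ont_rows("TOA", list(
    list(1, "assay", NULL),
    list(2, "molecular profiling assay", 1),
    list(3, "immunoprecipitation assay", 2),
    list(4, "ChIP-seq assay", 3),
    list(5, "histone modification ChIP-seq assay", 4),
    list(6, "chromatin accessibility assay", 2),
    list(7, "ATAC-seq assay", 6),
    list(8, "DNase-seq assay", 6),
    list(9, "expression profiling assay", 2),
    list(10, "RNA-seq assay", 9),
    list(11, "methylation profiling assay", 2),
    list(12, "whole-genome bisulfite sequencing assay", 11),
    list(13, "genotyping assay", 2),
    list(14, "genome-wide association study assay", 13),
    list(15, "sequence feature detection assay", 2),
    list(16, "transcription factor motif scan", 15),
    list(100, "data format", NULL),
    list(101, "binary track format", 100),
    list(102, "BigWig", 101),
    list(103, "BigBed", 101),
    list(104, "BCF", 101),
    list(105, "text track format", 100),
    list(106, "BED", 105),
    list(107, "bedGraph", 105),
    list(200, "biological target entity", NULL),
    list(201, "gene product", 200),
    list(202, "protein", 201),
    list(203, "messenger RNA", 201),
    list(204, "macromolecular structure", 200),
    list(205, "chromatin structure", 204),
    list(206, "sequence feature", 200),
    list(207, "transcription factor binding site", 206),
    list(208, "open chromatin region", 206))))
}

fixture_tos <- function() {
  # sample / phenotype stand-in ontology
  new_ontology_snapshot("tos", "2021-02-19", ont_rows("TOS", list(
    list(1, "biospecimen", NULL),
    list(2, "cell line", 1),
    list(3, "H1-hESC", 2),
    list(4, "K562", 2),
    list(5, "GM12878", 2),
    list(6, "cell type", 1),
    list(7, "lymphocyte", 6),
    list(8, "B cell", 7),
    list(9, "B cell, CD19 positive", 8),
    list(10, "T cell", 7),
    list(11, "abnormal cell type", 1),
    list(12, "leukemic cell", 11),
    list(13, "carcinoma cell", 11),
    list(14, "organism part", 1),
    list(15, "brain", 14),
    list(16, "liver", 14),
    list(17, "blood", 14),
    list(100, "phenotype", NULL),
    list(101, "disease", 100),
    list(102, "multiple sclerosis", 101),
    list(103, "chronic lymphocytic leukemia", 101),
    list(104, "normal phenotype", 100))))
}

fixture_tod <- function() {
  # data-use stand-in ontology
  new_ontology_snapshot("tod", "1.2", ont_rows("TOD", list(
    list(1, "data use condition", NULL),
    list(2, "permitted use", 1),
    list(3, "general research use", 2),
    list(4, "health or medical or biomedical research", 2),
    list(5, "no restriction", 2),
    list(6, "population origins or ancestry research", 2),
    list(7, "use limitation", 1),
    list(8, "disease specific research", 7),
    list(9, "project specific limitation", 7),
    list(10, "publication required", 7),
    list(11, "collaboration required", 7),
    list(12, "not for profit use only", 7),
    list(13, "ethics approval required", 7))))
}

fixture_curie_registry <- function() {
  data.frame(
    prefix = c("insdc.gca", "insdc.run", "taxonomy", "pubmed", "biosample",
               "hgnc", "ega.experiment"),
    pattern = c("^GC[AF]_[0-9]{9}\\.[0-9]+$", "^[SED]RR[0-9]{6,}$",
                "^[0-9]+$", "^[0-9]+$", "^SAM[NED][A-Z]?[0-9]+$",
                "^[0-9]+$", "^EGAX[0-9]{11}$"),
    url_template = c("https://example.org/asm/{accession}",
                     "https://example.org/run/{accession}",
                     "https://example.org/taxonomy/{accession}",
                     "https://example.org/pubmed/{accession}",
                     "https://example.org/biosample/{accession}",
                     "https://example.org/hgnc/{accession}",
                     "https://example.org/ega/experiment/{accession}"),
    stringsAsFactors = FALSE)
}

fixture_assemblies <- function() {
  new_assembly_table(
    canonical = c("GRCh37", "GRCh38", "GRCm38", "GRCm39"),
    synonyms = list("hg19", "hg38", "mm10", "mm39"),
    schemes = list("ucsc", "ucsc", "ucsc", "ucsc"),
    curies = c("insdc.gca:GCF_000001405.13", "insdc.gca:GCF_000001405.26",
               "insdc.gca:GCF_000001635.20", "insdc.gca:GCF_000001635.27"))
}

#' Build the packaged offline registry set
#'
#' Three versioned ontology snapshots (assay / sample / data-use
#' stand-ins), a CURIE prefix registry, and a genome-assembly synonym
#' table (including the canonical "GRCh37" / synonym "hg19" pair).
#' Content is fixed, not seeded.
#'
#' @return A `registry_set`.
#' @export
make_fixture_registries <- function() {
  snaps <- list(toa = fixture_toa(), tos = fixture_tos(),
                tod = fixture_tod())
  new_registry_set(fixture_curie_registry(), fixture_assemblies(), snaps)
}

# Cached default registries used when a caller passes none.
registry_cache <- new.env(parent = emptyenv())

#' Default registry set
#'
#' The packaged fixture registries, cached per session.  Supply your own
#' `registry_set` (e.g. from [load_registries()]) to validate against real
#' services' tables.
#' @return A `registry_set`.
#' @export
default_registries <- function() {
  if (is.null(registry_cache$reg)) {
    registry_cache$reg <- make_fixture_registries()
  }
  registry_cache$reg
}

# --- document generator ----------------------------------------------------

rpick <- function(x) if (length(x) <= 1L) x[[1]] else x[[sample.int(length(x), 1L)]]
rhex <- function(n) paste(sample(c(0:9, letters[1:6]), n, replace = TRUE),
                          collapse = "")
rdigits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

# term pair with the label included ~70% of the time (absent labels are
# what the augmenter is for)
rterm <- function(snapshot, iri, p_label = 0.7) {
  pair <- list(term_id = iri)
  if (stats::runif(1) < p_label) pair$term_label <- label_of(snapshot, iri)
  pair
}

maybe_extras <- function(obj, p = 0.1) {
  if (stats::runif(1) < p) {
    key <- rpick(c("lab_notebook", "internal_batch", "qc_comment"))
    obj[[key]] <- paste0("note-", rdigits(4))
  }
  obj
}

rcontact <- function(i) {
  ct <- list(name = sprintf("Curator %d", i),
             email = sprintf("curator%d@example.org", i))
  if (stats::runif(1) < 0.3) ct$url <- sprintf("https://example.org/people/%d", i)
  ct
}

#' Generate a deterministic valid document
#'
#' Every required attribute is populated, the reference graph is connected,
#' roughly 20% of experiments trace provenance through `aggregated_from`
#' chains instead of a direct sample link (with a chain of length >= 2
#' whenever `n_experiments >= 3`), and roughly 10% of objects carry unknown
#' extra fields.  The same seed always yields the same document, and the
#' result passes [validate_document()].
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_collections,n_studies,n_samples,n_experiments,n_tracks object
#'   counts (each >= 1).
#' @param registries registry set the document draws terms from.
#' @return A `track_doc`.
#' @export
make_valid_document <- function(seed, n_collections = 1L, n_studies = 2L,
                                n_samples = 3L, n_experiments = 5L,
                                n_tracks = 6L,
                                registries = default_registries()) {
  counts <- c(n_collections, n_studies, n_samples, n_experiments, n_tracks)
  if (any(counts < 1L)) tm_error("configuration", "all object counts must be >= 1")
  toa <- registries$ontologies$toa
  tos <- registries$ontologies$tos
  tod <- registries$ontologies$tod
  bios <- biospecimen_classes()

  with_seed(seed, {
    collections <- lapply(seq_len(n_collections), function(i) {
      maybe_extras(list(
        local_id = sprintf("coll_%d", i),
        name = sprintf("Regulatory element collection %d", i),
        description = sprintf("Uniformly processed track collection %d from seed %d", i, seed),
        source_url = sprintf("https://hub.example.org/coll%d/", i),
        contact = rcontact(i)))
    })

    studies <- lapply(seq_len(n_studies), function(i) {
      maybe_extras(list(
        local_id = sprintf("study_%d", i),
        collection_ref = sprintf("coll_%d", sample.int(n_collections, 1L)),
        name = sprintf("Chromatin state study %d", i),
        publications = lapply(seq_len(sample.int(2L, 1L)), function(j)
          paste0("pubmed:", rdigits(7))),
        contact = rcontact(100L + i)))
    })

    sample_children <- list(
      cell_line = paste0("TOS_", c(3, 4, 5)),
      cell_type = paste0("TOS_", c(8, 9, 10)),
      abnormal_cell_type = paste0("TOS_", c(12, 13)),
      organism_part = paste0("TOS_", c(15, 16, 17)))
    samples <- lapply(seq_len(n_samples), function(i) {
      cls <- ((i - 1L) %% 4L) + 1L   # rotate through the four classes
      child_field <- bios$child[cls]
      child_num <- as.integer(sub("TOS_", "", rpick(sample_children[[child_field]])))
      st <- list()
      st[[child_field]] <- rterm(tos, onto_iri("TOS", child_num))
      s <- list(
        local_id = sprintf("sample_%d", i),
        species = "taxonomy:9606",
        biospecimen_class = list(term_id = bios$term_id[cls],
                                 term_label = bios$label[cls]),
        sample_type = st)
      if (stats::runif(1) < 0.3) {
        s$phenotype <- rterm(tos, onto_iri("TOS", rpick(c(102, 103, 104))))
      }
      if (stats::runif(1) < 0.4) {
        s$external_refs <- list(paste0("biosample:SAMN", rdigits(8)))
      }
      maybe_extras(s)
    })

    # technique pool with coherent target recipes
    tech_pool <- list(
      list(num = 4,  cls = "gene"),      # ChIP-seq
      list(num = 5,  cls = "gene"),      # histone ChIP-seq
      list(num = 16, cls = "feature"),   # TF motif scan
      list(num = 14, cls = "phenotype"), # GWAS
      list(num = 7,  cls = "none"),      # ATAC-seq
      list(num = 10, cls = "none"),      # RNA-seq
      list(num = 12, cls = "none"))      # WGBS
    gene_pool <- list(c("hgnc:13723", "CTCF"), c("hgnc:7553", "MYC"),
                      c("hgnc:9966", "REST"))
    detail_pool <- c("", "", "phosphorylated S5", "trimethylated K4")

    n_agg <- if (n_experiments >= 3L) {
      max(2L, as.integer(round(0.2 * n_experiments)))
    } else 0L
    agg_idx <- if (n_agg > 0L) seq.int(n_experiments - n_agg + 1L, n_experiments)
               else integer()

    experiments <- lapply(seq_len(n_experiments), function(i) {
      tech <- rpick(tech_pool)
      target <- list()
      if (tech$cls == "gene") {
        g <- rpick(gene_pool)
        target$gene_id <- list(id = g[1], label = g[2])
        target$gene_product_type <- rterm(toa, onto_iri("TOA", 202))
        det <- rpick(detail_pool)
        if (nzchar(det)) target$target_details <- det
      } else if (tech$cls == "feature") {
        target$sequence_feature <- rterm(toa, onto_iri("TOA", rpick(c(207, 208))))
      } else if (tech$cls == "phenotype") {
        target$phenotype <- rterm(tos, onto_iri("TOS", rpick(c(102, 103))))
      }
      e <- list(
        local_id = sprintf("exp_%d", i),
        study_ref = sprintf("study_%d", sample.int(n_studies, 1L)),
        technique = rterm(toa, onto_iri("TOA", tech$num)),
        target = target,
        lab_protocol_description = sprintf("https://protocols.example.org/lab/%d", i),
        compute_protocol_description = sprintf("Peak calling pipeline v1.%d", i))
      if (i %in% agg_idx) {
        # upstream links point strictly backwards, so chains stay acyclic;
        # the last two aggregators form a chain of length >= 2
        e$aggregated_from <- as.list(unique(c(
          sprintf("exp_%d", i - 1L),
          if (stats::runif(1) < 0.3 && i > 2L)
            sprintf("exp_%d", sample.int(i - 2L, 1L)))))
      } else {
        e$sample_ref <- sprintf("sample_%d", sample.int(n_samples, 1L))
      }
      maybe_extras(e)
    })

    asm <- fixture_assemblies()
    canonicals <- unique(asm$canonical)[1:2]  # human assemblies
    format_nums <- c(102, 103, 106)
    tracks <- lapply(seq_len(n_tracks), function(i) {
      canon <- rpick(canonicals)
      entry <- asm[asm$canonical == canon, , drop = FALSE]
      name <- rpick(entry$name)
      fmt <- rpick(format_nums)
      tr <- list(
        local_id = sprintf("track_%d", i),
        source_coll_ref = sprintf("coll_%d", sample.int(n_collections, 1L)),
        experiment_ref = sprintf("exp_%d", sample.int(n_experiments, 1L)),
        file_url = sprintf("https://hub.example.org/s%d/track_%d.%s",
                           seed, i, c(`102` = "bw", `103` = "bb",
                                      `106` = "bed")[as.character(fmt)]),
        label_short = sprintf("Track %d", i),
        label_long = sprintf("Condensed signal track %d (seed %d)", i, seed),
        description = sprintf("Genome-wide features for track %d", i),
        assembly_id = entry$curie[1],
        annotation_name = name,
        raw_file_ids = lapply(seq_len(sample.int(2L, 1L)), function(j)
          paste0("insdc.run:SRR", rdigits(7))),
        file_format = rterm(toa, onto_iri("TOA", fmt)),
        type_of_condensed_data = rpick(tm_vocab("type_of_condensed_data")),
        genomic_track_type = rpick(tm_vocab("genomic_track_type")),
        checksum = list(method = "md5", value = rhex(32)))
      if (stats::runif(1) < 0.5) {
        tr$data_use_conditions <- list(
          rterm(tod, onto_iri("TOD", rpick(c(3, 4, 5, 8, 10)))))
        tr$data_use_url <- sprintf("https://example.org/dua/%d", i)
      }
      maybe_extras(tr)
    })

    doc_info <- list(
      local_id = sprintf("doc_%d", seed),
      version_id = "1.0.0",
      version_date = sprintf("2021-%02d-%02d", sample.int(12L, 1L),
                             sample.int(28L, 1L)),
      source_url = sprintf("https://hub.example.org/meta/doc_%d.json", seed),
      doi = sprintf("10.5072/synthetic.%06d", seed %% 1000000L))
    if (stats::runif(1) < 0.3) {
      doc_info$derived_from <- sprintf("10.5072/synthetic.parent.%06d",
                                       seed %% 1000000L)
    }

    structure(list(doc_info = doc_info, collections = collections,
                   studies = studies, samples = samples,
                   experiments = experiments, tracks = tracks),
              class = "track_doc")
  })
}

# --- rule-isolated invalid documents ---------------------------------------

#' Generate a document violating exactly one validator rule
#'
#' Starts from [make_valid_document()] with the same seed and injects one
#' minimal violation of the requested kind, so the resulting report
#' contains at least one issue and only issues of that kind.
#'
#' @param seed integer seed.
#' @param rule_kind one of [invalid_rule_kinds()].
#' @param ... forwarded to [make_valid_document()].
#' @return A `track_doc`.
#' @export
make_invalid_document <- function(seed, rule_kind, ...) {
  if (!(rule_kind %in% invalid_rule_kinds())) {
    tm_error("configuration",
             sprintf("unsupported rule kind '%s'", rule_kind))
  }
  doc <- make_valid_document(seed, ...)
  switch(rule_kind,
    unique_violation = {
      if (length(doc$samples) < 2L) {
        doc$samples[[2]] <- doc$samples[[1]]
      }
      old <- doc$samples[[2]]$local_id
      doc$samples[[2]]$local_id <- doc$samples[[1]]$local_id
      # re-point experiments at the surviving id so refs still resolve
      for (i in seq_along(doc$experiments)) {
        if (identical(doc$experiments[[i]]$sample_ref, old)) {
          doc$experiments[[i]]$sample_ref <- doc$samples[[1]]$local_id
        }
      }
      doc
    },
    foreign_ref = {
      doc$experiments[[1]]$sample_ref <- "sample_does_not_exist"
      doc
    },
    curie_syntax = {
      doc$samples[[1]]$species <- "no-colon-here"
      doc
    },
    curie_prefix = {
      doc$samples[[1]]$external_refs <- list("unregistered.prefix:123")
      doc
    },
    curie_accession = {
      doc$samples[[1]]$species <- "taxonomy:not-digits"
      doc
    },
    ontology_term = {
      doc$experiments[[1]]$technique <-
        list(term_id = onto_iri("TOA", 9999999))
      doc
    },
    ontology_ancestor = {
      # a real assay-snapshot term (a data format) outside the assay subtree
      doc$experiments[[1]]$technique <-
        list(term_id = onto_iri("TOA", 102), term_label = "BigWig")
      doc
    },
    ontology_label_mismatch = {
      doc$experiments[[1]]$technique$term_label <- "ChIPseq"
      doc
    },
    assembly_name = {
      doc$tracks[[1]]$annotation_name <- "mm10"
      doc
    },
    checksum_format = {
      doc$tracks[[1]]$checksum$value <-
        substr(doc$tracks[[1]]$checksum$value, 1L, 31L)
      doc
    },
    doi_format = {
      doc$doc_info$doi <- "11.1234/not.a.doi"
      doc
    },
    cardinality = {
      # experiment 1 is always sample-linked by construction; dropping the
      # link leaves neither sample_ref nor aggregated_from
      doc$experiments[[1]]$sample_ref <- NULL
      doc
    },
    aggregation_cycle = {
      e <- doc$experiments[[1]]
      e$sample_ref <- NULL
      e$aggregated_from <- list(e$local_id)  # minimal self-loop
      doc$experiments[[1]] <- e
      doc
    },
    biospecimen_child_missing = {
      bios <- biospecimen_classes()
      s <- doc$samples[[1]]
      j <- match(s$biospecimen_class$term_id, bios$term_id)
      s$sample_type[[bios$child[j]]] <- NULL
      doc$samples[[1]] <- s
      doc
    })
}

#' Rule kinds supported by [make_invalid_document()]
#'
#' Every validator rule kind except `schema` (structural violations are
#' covered by dedicated tests, not by the injector).
#' @return Character vector.
#' @export
invalid_rule_kinds <- function() {
  setdiff(validation_rule_kinds(), "schema")
}

# --- track hub fixtures ----------------------------------------------------

#' Generate a deterministic track-hub file set
#'
#' Produces hub.txt / genomes.txt / trackDb.txt contents with a mix of
#' container stanzas, leaf stanzas carrying a `bigDataUrl` and leaf
#' stanzas without one.
#'
#' @param seed integer seed.
#' @return A list with `hub_text`, `genomes_text`, `trackdb_texts` (named
#'   by genome) and `n_data_tracks` (the number of leaf stanzas carrying a
#'   data URL).
#' @export
make_fixture_hub <- function(seed) {
  with_seed(seed, {
    genomes <- if (stats::runif(1) < 0.5) "hg19" else c("hg19", "hg38")
    hub_text <- paste(
      sprintf("hub seedhub%d", seed),
      sprintf("shortLabel Seed hub %d", seed),
      sprintf("longLabel Synthetic track hub generated from seed %d", seed),
      "genomesFile genomes.txt",
      sprintf("email hubmaster%d@example.org", seed),
      sep = "\n")
    genomes_text <- paste(vapply(genomes, function(g)
      sprintf("genome %s\ntrackDb %s/trackDb.txt", g, g), character(1)),
      collapse = "\n\n")
    n_data <- 0L
    trackdb_texts <- lapply(genomes, function(g) {
      blocks <- character()
      n_leaf <- sample.int(4L, 1L)
      use_container <- stats::runif(1) < 0.5
      if (use_container) {
        blocks <- c(blocks, paste(
          sprintf("track composite_%s", g),
          "compositeTrack on",
          sprintf("shortLabel Composite %s", g),
          sprintf("longLabel Composite container for %s", g),
          "type bigWig", sep = "\n"))
      }
      for (i in seq_len(n_leaf)) {
        has_url <- stats::runif(1) < 0.8
        fmt <- rpick(c("bigWig", "bigBed", "customFormat"))
        lines <- c(sprintf("track %s_track_%d", g, i))
        if (use_container && stats::runif(1) < 0.5) {
          lines <- c(lines, sprintf("    parent composite_%s on", g))
        }
        lines <- c(lines,
                   sprintf("    shortLabel %s track %d", g, i),
                   sprintf("    longLabel Synthetic %s leaf track %d", g, i),
                   sprintf("    type %s", fmt))
        if (has_url) {
          n_data <<- n_data + 1L
          lines <- c(lines,
                     sprintf("    bigDataUrl https://hub.example.org/%s/t%d.%s",
                             g, i, fmt),
                     sprintf("    metadata assay=ChIP-seq batch=b%d", i))
        }
        blocks <- c(blocks, paste(lines, collapse = "\n"))
      }
      paste(blocks, collapse = "\n\n")
    })
    names(trackdb_texts) <- genomes
    list(hub_text = hub_text, genomes_text = genomes_text,
         trackdb_texts = trackdb_texts, n_data_tracks = n_data)
  })
}
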