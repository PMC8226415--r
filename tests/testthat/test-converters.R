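# Converters: GSuite export/import, track hub import.

test_that("to_gsuite produces one row per track with the dialect header", {
  d <- make_valid_document(1, n_tracks = 2)
  gt <- to_gsuite(d)
  expect_length(gt$rows, 2)
  expect_identical(gt$columns[1], "uri")
  txt <- format_gsuite(gt)
  expect_match(strsplit(txt, "\n")[[1]][1], "^###uri\t")
  # zero tracks: header only
  d0 <- make_valid_document(1)
  d0$tracks <- list()
  lines <- strsplit(format_gsuite(to_gsuite(d0)), "\n")[[1]]
  expect_length(lines, 1)
})

test_that("unaugmented documents export '.' in summary columns; augmented
           documents fill them (independent-walk check)", {
  d <- make_valid_document(23)
  gt <- to_gsuite(d)
  j <- match(c("target_summary", "sample_summary"), gt$columns)
  for (r in gt$rows) expect_true(all(is.na(r[j])))
  ga <- to_gsuite(augment_document(d, REG))
  sample_cells <- vapply(ga$rows, `[`, "", j[2])
  # sample-linked tracks must expose the sample summary after augmentation
  linked <- vapply(d$tracks, function(tr) {
    e <- Find(function(e) identical(e$local_id, tr$experiment_ref),
              d$experiments)
    !is.null(e$sample_ref)
  }, logical(1))
  expect_true(all(!is.na(sample_cells[linked])))
})

test_that("parse_gsuite: '.' means absent; format errors carry line numbers", {
  txt <- "###uri\ttitle\nhttps://x/1.bw\t.\n"
  gt <- parse_gsuite(txt)
  expect_true(is.na(gt$rows[[1]][2]))
  pd <- from_gsuite(txt, REG)
  expect_null(pd$tracks[[1]]$label_short)  # absent, not empty string
  err <- tryCatch(parse_gsuite("###uri\ttitle\nonly-one-field\n"),
                  error = identity)
  expect_s3_class(err, "trackmeta_gsuite_format")
  expect_match(conditionMessage(err), "line 2")
  expect_error(parse_gsuite("no header\nat all\n"),
               class = "trackmeta_gsuite_format")
})

test_that("GSuite round trip recovers the track subset exactly (40 seeds)", {
  for (seed in 1:40) {
    d <- make_valid_document(seed)
    pd <- from_gsuite(format_gsuite(to_gsuite(d)), REG)
    expect_length(pd$tracks, length(d$tracks))
    for (i in seq_along(d$tracks)) {
      tr <- d$tracks[[i]]; tr2 <- pd$tracks[[i]]
      expect_identical(tr2$file_url, tr$file_url)
      expect_identical(tr2$label_short, tr$label_short)
      expect_identical(tr2$annotation_name, tr$annotation_name)
      expect_identical(tr2$genomic_track_type, tr$genomic_track_type)
    }
  }
})

test_that("hub import maps stanza fields onto collection and tracks", {
  hub <- paste("hub demo", "shortLabel Demo hub", "longLabel A demo hub",
               "genomesFile genomes.txt", "email hub@example.org", sep = "\n")
  genomes <- "genome hg19\ntrackDb hg19/trackDb.txt"
  tdb <- paste(
    "track wig1",
    "    shortLabel Wig one",
    "    longLabel A bigWig leaf",
    "    type bigWig 0 1",
    "    bigDataUrl https://data.example.org/w1.bw",
    "    metadata assay=ChIP-seq cell=K562",
    sep = "\n")
  res <- import_trackhub(hub, genomes, list(hg19 = tdb), REG)
  doc <- res$document
  expect_length(doc$collections, 1)
  expect_identical(doc$collections[[1]]$name, "Demo hub")
  expect_identical(doc$collections[[1]]$contact$email, "hub@example.org")
  expect_length(doc$tracks, 1)
  tr <- doc$tracks[[1]]
  expect_identical(tr$file_url, "https://data.example.org/w1.bw")
  expect_identical(tr$label_short, "Wig one")
  expect_identical(tr$label_long, "A bigWig leaf")
  expect_identical(tr$annotation_name, "hg19")
  expect_identical(tr$assembly_id, "insdc.gca:GCF_000001405.13")
  expect_identical(tr$file_format$term_label, "BigWig")
  # metadata pairs kept as unknown fields
  expect_identical(tr$assay, "ChIP-seq")
  expect_identical(tr$cell, "K562")
})

test_that("container stanzas emit no track and are logged", {
  hub <- "hub c\nshortLabel C\nlongLabel CC\nemail c@example.org"
  genomes <- "genome hg19\ntrackDb t.txt"
  tdb <- paste(
    "track comp", "compositeTrack on", "shortLabel Comp", "type bigWig",
    "", "track leaf1", "    parent comp on", "    shortLabel L1",
    "    type bigWig", "    bigDataUrl https://x/l1.bw",
    "", "track nourl", "    shortLabel No URL", "    type bigWig",
    sep = "\n")
  res <- import_trackhub(hub, genomes, list(hg19 = tdb), REG)
  expect_length(res$document$tracks, 1)
  expect_identical(res$document$tracks[[1]]$local_id, "leaf1")
  expect_true(any(grepl("container", res$log)))
  expect_true(any(grepl("no bigDataUrl", res$log)))
})

test_that("import drafts fail validation with only missing-required issues", {
  h <- make_fixture_hub(5)
  res <- import_trackhub(h$hub_text, h$genomes_text, h$trackdb_texts, REG)
  r <- validate_document(res$document, REG)
  expect_false(r$ok)
  expect_identical(report_kinds(r), "schema")
  expect_true(all(grepl("^missing required",
                        vapply(r$issues, `[[`, "", "message"))))
})

test_that("hub import conservation: one track per leaf stanza with a data
           URL (independent stanza counter, 20 seeds)", {
  for (seed in 1:20) {
    h <- make_fixture_hub(seed)
    res <- import_trackhub(h$hub_text, h$genomes_text, h$trackdb_texts, REG)
    # independent counter: count bigDataUrl lines in the raw text
    n_urls <- sum(vapply(h$trackdb_texts, function(txt)
      length(grep("^\\s*bigDataUrl\\s", strsplit(txt, "\n")[[1]])),
      integer(1)))
    expect_length(res$document$tracks, n_urls)
    expect_identical(h$n_data_tracks, n_urls)
  }
})
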