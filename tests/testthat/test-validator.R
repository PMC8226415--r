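# Extended validator: schema + document-set rules, report determinism.

test_that("generator documents validate cleanly; reports are deterministic", {
  for (seed in c(3, 42, 77)) {
    r <- validate_document(make_valid_document(seed), REG)
    expect_true(r$ok)
    expect_length(r$issues, 0)
  }
  d <- make_invalid_document(8, "foreign_ref")
  expect_identical(report_json(validate_document(d, REG)),
                   report_json(validate_document(d, REG)))
})

test_that("constructed duplicate local_id yields exactly one unique issue", {
  d <- make_valid_document(5)
  d$samples[[2]]$local_id <- "S1"
  d$samples[[1]]$local_id <- "S1"
  for (i in seq_along(d$experiments)) {
    if (!is.null(d$experiments[[i]]$sample_ref)) {
      d$experiments[[i]]$sample_ref <- "S1"
    }
  }
  r <- validate_document(d, REG)
  expect_identical(report_kinds(r), "unique_violation")
  expect_length(r$issues, 1)
})

test_that("dangling reference yields exactly one foreign_ref issue", {
  d <- make_valid_document(5)
  d$experiments[[1]]$sample_ref <- "S99"
  r <- validate_document(d, REG)
  expect_identical(report_kinds(r), "foreign_ref")
  expect_length(r$issues, 1)
  expect_match(r$issues[[1]]$path, "^/experiments/0/sample_ref$")
})

test_that("ontology rules: missing term, ancestor violation, label mismatch", {
  snaps <- REG$ontologies
  d <- make_valid_document(9)
  # a valid technique under the assay root raises nothing
  expect_length(check_ontology_fields(d, snaps), 0)
  d1 <- d
  d1$experiments[[1]]$technique <-
    list(term_id = "https://onto.invalid/TOA_0000102")  # a data format term
  expect_identical(
    unique(vapply(check_ontology_fields(d1, snaps), `[[`, "", "rule_kind")),
    "ontology_ancestor")
  d2 <- d
  d2$experiments[[1]]$technique <- list(
    term_id = "https://onto.invalid/TOA_0000004", term_label = "ChIPseq")
  iss <- check_ontology_fields(d2, snaps)
  expect_identical(unique(vapply(iss, `[[`, "", "rule_kind")),
                   "ontology_label_mismatch")
  expect_match(iss[[1]]$message, "ChIP-seq assay")
})

test_that("aggregation cycles: self-loop flagged, chains pass, oracle agrees", {
  d <- make_valid_document(6)
  e <- d$experiments[[1]]
  e$sample_ref <- NULL
  e$aggregated_from <- list(e$local_id)
  d$experiments[[1]] <- e
  iss <- check_aggregation_acyclic(d)
  expect_length(iss, 1)
  expect_identical(iss[[1]]$rule_kind, "aggregation_cycle")
  # a linear chain raises nothing (generator builds one for n >= 3)
  expect_length(check_aggregation_acyclic(make_valid_document(6)), 0)

  # random 30-experiment graphs vs matrix-closure cycle participants
  for (seed in 1:6) {
    set.seed(seed)
    n <- 30
    adj <- matrix(stats::runif(n * n) < 0.06, n, n)
    doc <- list(experiments = lapply(seq_len(n), function(i) {
      list(local_id = sprintf("e%d", i),
           aggregated_from = as.list(sprintf("e%d", which(adj[i, ]))))
    }))
    flagged <- sort(vapply(check_aggregation_acyclic(doc), function(i)
      as.integer(sub("^/experiments/(\\d+)/.*$", "\\1", i$path)) + 1L,
      integer(1)))
    expected <- which(diag(closure_oracle(adj)))
    expect_identical(flagged, expected, label = sprintf("graph seed %d", seed))
  }
})

test_that("assembly, checksum, DOI and cardinality rules fire in isolation", {
  d <- make_valid_document(10)
  d$tracks[[1]]$annotation_name <- "mm10"
  expect_identical(report_kinds(validate_document(d, REG)), "assembly_name")

  d <- make_valid_document(10)
  d$tracks[[1]]$checksum <- list(method = "sha1", value = strrep("a", 39))
  expect_identical(report_kinds(validate_document(d, REG)), "checksum_format")

  d <- make_valid_document(10)
  d$doc_info$doi <- "not-a-doi"
  expect_identical(report_kinds(validate_document(d, REG)), "doi_format")

  d <- make_valid_document(10)
  d$experiments[[1]]$aggregated_from <-
    list(d$experiments[[2]]$local_id, d$experiments[[2]]$local_id)
  d$experiments[[1]]$sample_ref <- NULL
  expect_identical(report_kinds(validate_document(d, REG)), "cardinality")
})

test_that("biospecimen class selects a mandatory sample_type child", {
  d <- make_valid_document(13)
  s <- d$samples[[1]]
  cls_id <- s$biospecimen_class$term_id
  child <- trackmeta:::biospecimen_classes()
  key <- child$child[match(cls_id, child$term_id)]
  s$sample_type[[key]] <- NULL
  d$samples[[1]] <- s
  expect_identical(report_kinds(validate_document(d, REG)),
                   "biospecimen_child_missing")
})

test_that("unknown extra fields never produce issues", {
  d <- make_valid_document(14)
  d$weird_top_level <- list(a = 1)
  d$doc_info$curator_mood <- "optimistic"
  d$tracks[[1]]$display_settings <- list(color = "128,0,0")
  expect_true(validate_document(d, REG)$ok)
})

test_that("issues are ordered by (path, rule_kind) and ok mirrors emptiness", {
  d <- make_valid_document(15)
  d$doc_info$doi <- "bad"
  d$experiments[[1]]$sample_ref <- "missing"
  d$samples[[2]]$species <- "nocolon"
  r <- validate_document(d, REG)
  expect_false(r$ok)
  keys <- vapply(r$issues, function(i) paste0(i$path, "\r", i$rule_kind), "")
  expect_identical(keys, sort(keys, method = "radix"))
})
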