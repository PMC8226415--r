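# Augmentation: labels, version capture, summaries, provenance,
# idempotence, non-destructiveness.

test_that("augmentation is idempotent and preserves validity (25 seeds)", {
  for (seed in 1:25) {
    d <- make_valid_document(seed)
    a <- augment_document(d, REG)
    expect_true(validate_document(a, REG)$ok, label = sprintf("seed %d", seed))
    expect_true(document_equal(augment_document(a, REG), a),
                label = sprintf("idempotence seed %d", seed))
  }
})

test_that("augmentation is non-destructive (tree-diff oracle)", {
  owned <- "(/term_label|/summary|/ontology_versions(/|=)|/augmented_from)"
  for (seed in c(2, 21, 60)) {
    d <- make_valid_document(seed)
    a <- augment_document(d, REG)
    before <- flat_fields(d)
    after <- flat_fields(a)
    # every submitted (path, value) survives unchanged...
    expect_true(all(before %in% after), label = sprintf("seed %d", seed))
    # ...and everything new is augmentation-owned
    new <- setdiff(after, before)
    expect_true(all(grepl(owned, new)), label = paste(new, collapse = "; "))
  }
})

test_that("ontology versions capture exactly the snapshots referenced", {
  # hand-built minimal document drawing terms from toa and tos only
  d <- make_valid_document(30)
  for (i in seq_along(d$tracks)) d$tracks[[i]]$data_use_conditions <- NULL
  expect_true(validate_document(d, REG)$ok)
  a <- augment_document(d, REG)
  expect_identical(names(a$doc_info$ontology_versions), c("toa", "tos"))
  expect_identical(a$doc_info$ontology_versions$toa,
                   REG$ontologies$toa$version)
  # with a data-use term present, all three appear
  d$tracks[[1]]$data_use_conditions <-
    list(list(term_id = "https://onto.invalid/TOD_0000003"))
  a2 <- augment_document(d, REG)
  expect_identical(names(a2$doc_info$ontology_versions),
                   c("toa", "tod", "tos"))
})

test_that("labels are filled from snapshots; provenance prefers the DOI", {
  d <- make_valid_document(31)
  d$experiments[[1]]$technique <-
    list(term_id = "https://onto.invalid/TOA_0000004")  # label omitted
  a <- augment_document(d, REG)
  expect_identical(a$experiments[[1]]$technique$term_label, "ChIP-seq assay")
  expect_identical(a$doc_info$augmented_from, d$doc_info$doi)
  d$doc_info$doi <- NULL
  a2 <- augment_document(d, REG, force = TRUE)
  expect_identical(a2$doc_info$augmented_from, d$doc_info$version_id)
})

test_that("sample_type summary follows the biospecimen class rule table", {
  mk <- function(class_num, label, child, child_id, child_label) {
    list(biospecimen_class = list(
           term_id = sprintf("https://onto.invalid/TOS_%07d", class_num),
           term_label = label),
         sample_type = stats::setNames(
           list(list(term_id = child_id, term_label = child_label)), child))
  }
  expect_identical(
    summarize_sample_type(mk(2, "cell line", "cell_line",
                             "https://onto.invalid/TOS_0000003", "H1-hESC")),
    "H1-hESC")
  expect_identical(
    summarize_sample_type(mk(6, "cell type", "cell_type",
                             "https://onto.invalid/TOS_0000009",
                             "B cell, CD19 positive")),
    "B cell, CD19 positive")
  s <- mk(2, "cell line", "cell_type",
          "https://onto.invalid/TOS_0000009", "B cell, CD19 positive")
  expect_error(summarize_sample_type(s),
               class = "trackmeta_biospecimen_child_missing")
})

test_that("target summary follows the technique rule table", {
  chip <- list(term_id = "https://onto.invalid/TOA_0000004")
  atac <- list(term_id = "https://onto.invalid/TOA_0000007")
  motif <- list(term_id = "https://onto.invalid/TOA_0000016")
  gwas <- list(term_id = "https://onto.invalid/TOA_0000014")
  exp1 <- list(technique = chip,
               target = list(gene_id = list(id = "hgnc:13723", label = "CTCF")))
  expect_identical(summarize_target(exp1, REG), "CTCF")
  exp2 <- exp1
  exp2$target$target_details <- "phosphorylated"
  expect_identical(summarize_target(exp2, REG), "CTCF phosphorylated")
  expect_identical(summarize_target(list(technique = atac, target = list()),
                                    REG), "")
  expect_identical(
    summarize_target(list(technique = motif, target = list(
      sequence_feature = list(term_id = "https://onto.invalid/TOA_0000207",
                              term_label = "transcription factor binding site"))),
      REG),
    "transcription factor binding site")
  expect_identical(
    summarize_target(list(technique = gwas, target = list(
      phenotype = list(term_id = "https://onto.invalid/TOS_0000102",
                       term_label = "multiple sclerosis"))), REG),
    "multiple sclerosis")
  expect_error(summarize_target(list(technique = chip, target = list()), REG),
               class = "trackmeta_target_child_missing")
})

test_that("augmentation refuses invalid input unless forced", {
  bad <- make_invalid_document(3, "foreign_ref")
  err <- tryCatch(augment_document(bad, REG), error = identity)
  expect_s3_class(err, "trackmeta_augmentation_refused")
  expect_match(conditionMessage(err), "foreign_ref")
  expect_s3_class(augment_document(bad, REG, force = TRUE), "track_doc")
})
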