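# Registry stand-ins: CURIE parsing/resolution, DOI syntax, assembly
# synonyms, ontology snapshots.

test_that("parse_curie splits at the first colon", {
  expect_identical(parse_curie("insdc.gca:GCF_000001405.13"),
                   list(prefix = "insdc.gca",
                        accession = "GCF_000001405.13"))
  expect_identical(parse_curie("a:b"), list(prefix = "a", accession = "b"))
  # accession may itself contain colons
  expect_identical(parse_curie("a:b:c")$accession, "b:c")
  expect_error(parse_curie("nocolon"), class = "trackmeta_curie_syntax")
  expect_error(parse_curie(":x"), class = "trackmeta_curie_syntax")
  expect_error(parse_curie("x:"), class = "trackmeta_curie_syntax")
})

test_that("resolve_curie substitutes the template; failures are typed", {
  # independent string build of the expected URL
  acc <- "GCF_000001405.13"
  expect_identical(resolve_curie(paste0("insdc.gca:", acc), REG),
                   paste0("https://example.org/asm/", acc))
  expect_error(resolve_curie("zzz:1", REG), class = "trackmeta_curie_prefix")
  expect_error(resolve_curie("insdc.gca:NOT_AN_ACC", REG),
               class = "trackmeta_curie_accession")
})

test_that("resolution implies parseability (monotone strictness)", {
  cases <- c("insdc.gca:GCF_000001405.13", "taxonomy:9606", "pubmed:123",
             "nocolon", ":bad", "bad:", "zzz:1", "hgnc:CTCF")
  for (s in cases) {
    resolved <- !inherits(tryCatch(resolve_curie(s, REG), error = identity),
                          "error")
    parsed <- !inherits(tryCatch(parse_curie(s), error = identity), "error")
    if (resolved) expect_true(parsed, label = s)
  }
})

test_that("DOI syntax accepts 10.x/y, strips doi: scheme, rejects others", {
  expect_true(validate_doi("10.1234/abc.v2"))
  expect_true(validate_doi("doi:10.1234/abc"))
  expect_true(validate_doi("  10.5072/zenodo.123  "))
  expect_false(validate_doi("11.1234/abc"))
  expect_false(validate_doi("10./abc"))
  expect_false(validate_doi("10.1234"))
  expect_false(validate_doi(""))
})

test_that("assembly normalization maps names and synonyms with scheme", {
  expect_identical(normalize_assembly("hg19", REG)[c(1, 2)],
                   list(canonical_name = "GRCh37", naming_scheme = "ucsc"))
  expect_identical(normalize_assembly("GRCh37", REG)[c(1, 2)],
                   list(canonical_name = "GRCh37", naming_scheme = "grc"))
  expect_error(normalize_assembly("madeUpAsm1", REG),
               class = "trackmeta_unknown_assembly")
  # idempotent on the canonical name
  for (n in c("hg19", "hg38", "GRCm38", "mm39")) {
    canon <- normalize_assembly(n, REG)$canonical_name
    expect_identical(normalize_assembly(canon, REG)$canonical_name, canon)
  }
})

test_that("ontology snapshots: labels, descendance, cycles, TSV round trip", {
  toa <- REG$ontologies$toa
  chip <- "https://onto.invalid/TOA_0000004"
  assay <- "https://onto.invalid/TOA_0000001"
  expect_identical(label_of(toa, chip), "ChIP-seq assay")
  expect_error(label_of(toa, "https://onto.invalid/TOA_9999999"),
               class = "trackmeta_ontology_term")
  expect_true(is_descendant(toa, chip, assay))
  expect_false(is_descendant(toa, assay, chip))
  expect_false(is_descendant(toa, chip, chip))  # reflexive-false
  # cycle rejected at construction
  bad <- data.frame(iri = c("a", "b"), label = c("a", "b"),
                    parents = c("b", "a"), stringsAsFactors = FALSE)
  expect_error(new_ontology_snapshot("cyc", "0", bad),
               class = "trackmeta_ontology_cycle")
  # TSV write/load round trip for the whole registry set
  dir <- tempfile("regdir")
  write_registries(REG, dir)
  reg2 <- load_registries(dir)
  expect_identical(reg2$curie, REG$curie)
  expect_identical(reg2$assemblies, REG$assemblies)
  for (nm in names(REG$ontologies)) {
    expect_identical(reg2$ontologies[[nm]]$version, REG$ontologies[[nm]]$version)
    expect_identical(reg2$ontologies[[nm]]$terms, REG$ontologies[[nm]]$terms)
  }
})

test_that("is_descendant equals matrix-closure reachability on random DAGs", {
  for (seed in 1:4) {
    fx <- random_dag_snapshot(seed, n = 50)
    reach <- closure_oracle(fx$adj)
    set.seed(seed + 1000)
    pairs <- cbind(sample.int(50, 60, replace = TRUE),
                   sample.int(50, 60, replace = TRUE))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      expect_identical(is_descendant(fx$snapshot, fx$iris[i], fx$iris[j]),
                       unname(reach[i, j]),
                       label = sprintf("seed %d pair %d->%d", seed, i, j))
    }
  }
})
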