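test_that("use-record ingestion keeps fields and flags malformed input", {
  path <- write_records_file(toy_records())
  recs <- read_use_records(path)
  expect_equal(nrow(recs), 3)
  expect_named(recs, c("taxon", "region", "category", "condition", "source"))

  odd <- toy_records()
  odd$region[1] <- "Atlantis"  # unknown region kept verbatim
  recs <- read_use_records(write_records_file(odd))
  expect_identical(recs$region[1], "Atlantis")

  empty <- toy_records()[0, ]
  expect_warning(recs <- read_use_records(write_records_file(empty)), "no use records")
  expect_equal(nrow(recs), 0)

  bad <- data.frame(species = "T1", use = "Skin")
  expect_error(read_use_records(write_records_file(bad)), "taxon.*category|category.*taxon")
})

test_that("category assignment canonicalizes case and synonyms", {
  recs <- data.frame(taxon = c("T1", "T2", "T3"), region = NA,
                     category = c("skin", "fever", "witchcraft"),
                     condition = NA, source = NA, stringsAsFactors = FALSE)
  expect_warning(out <- assign_categories(recs), "witchcraft")
  expect_identical(out$category, c("Skin", "Infections/Fever", "witchcraft"))
  expect_identical(attr(out, "unmatched"), "witchcraft")
  expect_error(assign_categories(recs, strict = TRUE), "witchcraft")
  vocab <- use_category_vocabulary()
  expect_length(vocab$canonical, 13)
})

test_that("community matrix construction is idempotent and order-invariant", {
  recs <- data.frame(taxon = c("T1", "T2", "T1"), region = NA,
                     category = c("Skin", "Skin", "Pain"),
                     condition = NA, source = NA, stringsAsFactors = FALSE)
  cm <- build_community_matrix(recs)
  expect_identical(sort(colnames(cm)[cm["Skin", ] == 1]), c("T1", "T2"))
  expect_identical(colnames(cm)[cm["Pain", ] == 1], "T1")
  expect_identical(sort(colnames(cm)[cm["Medicinal uses overall", ] == 1]),
                   c("T1", "T2"))
  # duplicated records and permuted row order change nothing
  expect_identical(build_community_matrix(recs[c(3, 1, 2, 1), ]), cm)
  # every sample is a subset of the overall sample
  expect_true(all(t(cm) <= cm["Medicinal uses overall", ]))
})

test_that("condition-level samples are matched on the condition field", {
  recs <- data.frame(taxon = c("T1", "T2"), region = NA,
                     category = c("Infections/Fever", "Skin"),
                     condition = c("Malaria", NA), source = NA,
                     stringsAsFactors = FALSE)
  cm <- build_community_matrix(recs, condition_samples = "malaria")
  expect_equal(sum(cm["malaria", ]), 1)
  expect_identical(colnames(cm)[cm["malaria", ] == 1], "T1")
})

test_that("wide presence matrices are accepted and non-binary cells rejected", {
  wide <- data.frame(taxon = c("T1", "T2"), Skin = c(1, 1), Pain = c(1, 0))
  cm <- build_community_matrix(wide = wide)
  expect_equal(unname(cm["Skin", c("T1", "T2")]), c(1L, 1L))
  wide$Pain[2] <- 2
  expect_error(build_community_matrix(wide = wide), "non-binary.*Pain")
})

test_that("phylocom sample files round-trip through presence collapse", {
  f <- tempfile()
  writeLines(c("Skin\t1\tT1"), f)
  cm <- read_phylocom_samples(f)
  expect_equal(dim(cm), c(1L, 1L))
  writeLines(c("Skin\t5\tT1", "Skin\t1\tT1", "Pain\t2\tT2"), f)
  cm <- read_phylocom_samples(f)
  expect_equal(unname(cm["Skin", "T1"]), 1L)  # abundance collapsed, dups merged
  expect_equal(sum(cm), 2L)
  writeLines(c("Skin\t1"), f)
  expect_error(read_phylocom_samples(f), "line 1")
  # round-trip identity
  recs <- toy_records()
  cm <- build_community_matrix(recs)
  write_phylocom_samples(cm, f)
  cm2 <- read_phylocom_samples(f)
  expect_identical(cm2[rownames(cm), colnames(cm)], unclass(cm)[, ])
})

test_that("use tallies and per-region proportions are consistent", {
  recs <- toy_records()
  tal <- tally_uses(recs, "taxon")
  expect_identical(tal$taxon, c("T1", "T2"))
  expect_identical(tal$uses, c(2L, 1L))

  many <- data.frame(taxon = "T1", region = "Neotropics",
                     category = c("Skin", "Skin", "Skin", "Pain"),
                     condition = NA, source = NA, stringsAsFactors = FALSE)
  prop <- relative_usage_by_region(many)
  expect_equal(unname(prop["Neotropics", c("Skin", "Pain")]), c(0.75, 0.25))
  expect_equal(unname(rowSums(prop)), rep(1, nrow(prop)), tolerance = 1e-12)
  # record order must not matter
  expect_identical(relative_usage_by_region(many[sample(4), ]), prop)
  noreg <- many
  noreg$region <- NA
  expect_error(suppressWarnings(relative_usage_by_region(noreg)), "no records")
})

test_that("taxon-to-tip matching expands species to accession tips", {
  tr <- read_phylogeny(text = "((Pa1:1,Pa2:1):1,(Pb:1,Pc:1):1);")
  cm <- build_community_matrix(data.frame(
    taxon = c("Pa", "Pb"), region = NA, category = "Skin",
    condition = NA, source = NA))
  mapping <- data.frame(taxon = c("Pa", "Pa"), tip = c("Pa1", "Pa2"))
  out <- match_taxa_to_tips(cm, tr, mapping = mapping)
  expect_equal(unname(out["Skin", c("Pa1", "Pa2", "Pb", "Pc")]),
               c(1L, 1L, 1L, 0L))
  expect_error(match_taxa_to_tips(cm, tr), "Pa")
  expect_warning(out2 <- match_taxa_to_tips(cm, tr, prune_unmatched = TRUE),
                 "dropped")
  expect_equal(sum(out2["Skin", ]), 1)
})
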