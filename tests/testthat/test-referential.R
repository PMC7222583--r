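# Referential analysis: concept mapping with dysonym suppression, gene
# alias mapping, and negated-mention detection.

mapped_ids <- function(sent) {
  unlist(lapply(sent$phrases, function(p)
    vapply(p$mappings, `[[`, "", "concept_id")))
}

test_that("dysonym-suppressed synonyms never surface in mappings", {
  s <- annotate_one("Influenza was diagnosed.")
  expect_equal(intersect(mapped_ids(s), c("C0021400", "C0021403")), "C0021400")
  # the full synonym still reaches the vaccine concept
  s2 <- annotate_one("Influenza virus vaccine was administered.")
  expect_true("C0021403" %in% mapped_ids(s2))
  # explicit-list dysonyms are suppressed too
  s3 <- annotate_one("The best outcome was achieved.")
  expect_false("C0339510" %in% mapped_ids(s3))
  s4 <- annotate_one("Vitelliform dystrophy was diagnosed.")
  expect_true("C0339510" %in% mapped_ids(s4))
})

test_that("longest-match wins and same-span ties use the hook", {
  s <- annotate_one("Ascending urinary tract infection was confirmed.")
  syns <- unlist(lapply(s$phrases, function(p)
    vapply(p$mappings, `[[`, "", "synonym")))
  expect_true("urinary tract infection" %in% tolower(syns))
  expect_false("infection" %in% tolower(syns))
  # pluggable same-span disambiguation
  kb_amb <- local({
    kb <- test_kb
    kb$synonyms <- rbind(kb$synonyms,
      data.frame(surface = "ambiterm", id = c("C1000001", "C1000002")))
    rebuild_kb_indexes(kb)
  })
  tk <- disambiguate_pos(lexicon_lookup(tokenize("ambiterm"), kb_amb))
  ph <- chunk_phrases(tk)
  m_default <- map_concepts(ph[[1]], tk, "ambiterm", kb_amb)
  expect_equal(m_default[[1]]$concept_id, "C1000001")  # lexicographic default
  m_hook <- map_concepts(ph[[1]], tk, "ambiterm", kb_amb,
                         disambiguator = function(ids, kb) sort(ids)[2])
  expect_equal(m_hook[[1]]$concept_id, "C1000002")
})

test_that("gene aliases map exactly, keep all hits, and coexist with dictionary", {
  s <- annotate_one("Ataxin-10 interacts with O-GlcNAc transferase OGT.")
  maps <- unlist(lapply(s$phrases, function(p) p$mappings), recursive = FALSE)
  ids <- vapply(maps, `[[`, "", "concept_id")
  srcs <- vapply(maps, `[[`, "", "source")
  expect_true("C1538308" %in% ids[srcs == "METATHESAURUS"])
  expect_true("25814" %in% ids[srcs == "GENE"])
  expect_true("8473" %in% ids[srcs == "GENE"])
  expect_true(all(vapply(maps[srcs == "GENE"], function(m)
    identical(m$semtypes, "Gene or Genome"), logical(1))))
  expect_false("C1538308" %in% ids[srcs == "GENE"])
  s2 <- annotate_one("ZZZX9 was overexpressed.")
  expect_length(mapped_ids(s2), 0L)
})

test_that("an alias shared by two genes yields two mappings", {
  kb2 <- local({
    kb <- test_kb
    kb$gene_index <- rbind(kb$gene_index,
      data.frame(alias = "shared1", gene_id = c("101", "202"),
                 symbol = c("GENEA", "GENEB")))
    rebuild_kb_indexes(kb)
  })
  s <- annotate_one("Shared1 was expressed.", kb = kb2)
  ids <- mapped_ids(s)
  expect_true(all(c("101", "202") %in% ids))
})

test_that("negated mentions respect the 2-concept window and pseudo-negation", {
  s <- annotate_one("There was no evidence of infection after gastroplasty.")
  maps <- unlist(lapply(s$phrases, function(p) p$mappings), recursive = FALSE)
  inf <- maps[[which(vapply(maps, `[[`, "", "concept_id") == "C1000044")]]
  expect_true(inf$negated)
  # a concept beyond the window of 2 is not flagged
  s2 <- annotate_one(
    "No evidence of infection, cystitis or pyelonephritis in cattle.")
  maps2 <- unlist(lapply(s2$phrases, function(p) p$mappings), recursive = FALSE)
  negd <- vapply(maps2, `[[`, TRUE, "negated")
  ids2 <- vapply(maps2, `[[`, "", "concept_id")
  expect_true(all(negd[ids2 %in% c("C1000044", "C1000007")]))
  expect_false(any(negd[ids2 == "C1000009"]))  # cattle, 4th concept
  # no triggers, no flags
  s3 <- annotate_one("Aspirin treats headache.")
  maps3 <- unlist(lapply(s3$phrases, function(p) p$mappings), recursive = FALSE)
  expect_false(any(vapply(maps3, `[[`, TRUE, "negated")))
  # pseudo-negation is exempt
  s4 <- annotate_one("Not only aspirin relieves headache.")
  maps4 <- unlist(lapply(s4$phrases, function(p) p$mappings), recursive = FALSE)
  expect_false(any(vapply(maps4, `[[`, TRUE, "negated")))
})

test_that("mapping is deterministic for identical input", {
  a <- annotate_one("Cystitis, urethritis and pyelonephritis in cattle.")
  b <- annotate_one("Cystitis, urethritis and pyelonephritis in cattle.")
  expect_identical(lapply(a$phrases, `[[`, "mappings"),
                   lapply(b$phrases, `[[`, "mappings"))
})
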