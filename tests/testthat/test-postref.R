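# Post-referential analysis: empty heads, NP compatibility, coordination,
# sortal anaphora.

sem_head_text <- function(text) {
  s <- annotate_one(text)
  np <- Filter(function(p) p$kind %in% c("NP", "PP") && !is.na(p$head), s$phrases)
  vapply(np, function(p) s$tokens$text[p$sem_head], "")
}

test_that("empty-head marking relabels the left modifier as semantic head", {
  s <- annotate_one("Activation of CYP2C9 variants by dapsone was studied.")
  pp <- Filter(function(p) !is.na(p$head) &&
                 s$tokens$text[p$head] == "variants", s$phrases)[[1]]
  expect_equal(s$tokens$text[pp$sem_head], "CYP2C9")
  # an informative head stays put
  s2 <- annotate_one("A lacunar infarction was seen.")
  np2 <- Filter(function(p) p$kind == "NP" && !is.na(p$head), s2$phrases)[[1]]
  expect_equal(s2$tokens$text[np2$sem_head], "infarction")
  # measurement word from the list
  expect_true("drug" %in% sem_head_text("The drug concentration was measured."))
  # never fires without a modifier
  s3 <- annotate_one("Variants were found.")
  np3 <- Filter(function(p) p$kind == "NP", s3$phrases)[[1]]
  expect_equal(np3$sem_head, np3$head)
})

test_that("NP compatibility covers group, head word, and relational nouns", {
  s <- annotate_one("Osteosarcoma and melanoma were studied.")
  nps <- which(vapply(s$phrases, function(p) p$kind == "NP" &&
                        length(p$mappings) > 0, logical(1)))
  expect_true(np_compatible(s$phrases[[nps[1]]], s$phrases[[nps[2]]],
                            s$tokens, s$tokens, test_kb))
  s2 <- annotate_one("Breast cancer and lung cancer were studied.")
  nps2 <- which(vapply(s2$phrases, function(p) p$kind == "NP" &&
                         !is.na(p$head), logical(1)))
  expect_true(np_compatible(s2$phrases[[nps2[1]]], s2$phrases[[nps2[2]]],
                            s2$tokens, s2$tokens, test_kb))
  s3 <- annotate_one("The analysis and the application were performed.")
  nps3 <- which(vapply(s3$phrases, function(p) p$kind == "NP" &&
                         !is.na(p$head), logical(1)))
  expect_true(np_compatible(s3$phrases[[nps3[1]]], s3$phrases[[nps3[2]]],
                            s3$tokens, s3$tokens, test_kb))
  # different groups, different heads, not relational: incompatible
  s4 <- annotate_one("Melanoma and aspirin were studied.")
  nps4 <- which(vapply(s4$phrases, function(p) p$kind == "NP" &&
                         length(p$mappings) > 0, logical(1)))
  expect_false(np_compatible(s4$phrases[[nps4[1]]], s4$phrases[[nps4[2]]],
                             s4$tokens, s4$tokens, test_kb))
})

test_that("series coordination collects compatible comma-separated conjuncts", {
  s <- annotate_one("Osteosarcoma, melanoma, and breast cancer were studied.")
  expect_length(s$coordinations, 1L)
  conj_names <- vapply(s$coordinations[[1]]$conjuncts, function(p)
    phrase_best_mapping(s$phrases[[p]])$name, "")
  expect_equal(conj_names, c("Osteosarcoma", "Melanoma", "Breast Carcinoma"))

  s2 <- annotate_one("Cystitis, urethritis and pyelonephritis were treated.")
  expect_length(s2$coordinations, 1L)
  expect_length(s2$coordinations[[1]]$conjuncts, 3L)

  # a conjunction joining verb phrases builds no NP coordination
  s3 <- annotate_one("Aspirin was administered and was compared.")
  expect_length(s3$coordinations, 0L)

  # an incompatible NP terminates leftward extension
  s4 <- annotate_one("Aspirin, melanoma and breast cancer were studied.")
  expect_length(s4$coordinations, 1L)
  expect_length(s4$coordinations[[1]]$conjuncts, 2L)
})

test_that("simple sortal anaphora links to the nearest valid antecedent", {
  res <- run_one(paste("Cetirizine was administered to patients.",
                       "This drug relieved symptoms."), anaphora = TRUE)
  expect_length(res$anaphor_links, 1L)
  l <- res$anaphor_links[[1]]
  expect_equal(l$kind, "SIMPLE")
  ant <- res$sentences[[l$antecedents[[1]][1]]]$phrases[[l$antecedents[[1]][2]]]
  expect_equal(phrase_best_mapping(ant)$name, "Cetirizine")
})

test_that("appositive constructions are filtered from anaphor candidates", {
  res <- run_one("The gene, BRCA1, was sequenced.", anaphora = TRUE)
  expect_length(res$anaphor_links, 0L)
})

test_that("number agreement gates linking", {
  # plural anaphor, singular antecedent: no link
  res <- run_one(paste("Cetirizine was administered.",
                       "These drugs relieved symptoms."), anaphora = TRUE)
  expect_length(res$anaphor_links, 0L)
})

test_that("plural anaphor over a coordination yields set membership", {
  res <- run_one(paste(
    "Epoprostenol, endothelin receptor antagonists, and",
    "phosphodiesterase type 5 inhibitors were approved.",
    "These drugs are effective."), anaphora = TRUE)
  expect_length(res$anaphor_links, 1L)
  l <- res$anaphor_links[[1]]
  expect_equal(l$kind, "SET_MEMBERSHIP")
  expect_length(l$antecedents, 3L)
  # every antecedent concept is a hierarchy descendant of the anaphor concept
  an <- res$sentences[[l$anaphor[1]]]$phrases[[l$anaphor[2]]]
  am <- phrase_best_mapping(an)
  for (a in l$antecedents) {
    cm <- phrase_best_mapping(res$sentences[[a[1]]]$phrases[[a[2]]])
    expect_true(is_ancestor(test_kb, am$concept_id, cm$concept_id))
  }
})
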