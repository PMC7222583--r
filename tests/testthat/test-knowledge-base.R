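# Knowledge-base loaders, licensing queries, dysonym logic, and domain
# extensions.

test_that("ontology loader parses triples, deduplicates, and validates labels", {
  f <- write_lines_tmp(c(
    "Pharmacologic Substance-TREATS-Disease or Syndrome",
    "# a comment",
    "",
    "Pharmacologic Substance-TREATS-Disease or Syndrome",
    "Body Part, Organ, or Organ Component-LOCATION_OF-Disease or Syndrome"))
  ont <- read_ontology(f)
  expect_equal(nrow(ont), 2L)
  expect_equal(ont$subject_type[1], "Pharmacologic Substance")
  expect_equal(ont$predicate[1], "TREATS")
  expect_equal(ont$object_type[1], "Disease or Syndrome")

  expect_equal(nrow(read_ontology(write_lines_tmp(character()))), 0L)
  expect_error(read_ontology(write_lines_tmp("Foo-NOT_A_PREDICATE-Bar")),
               "NOT_A_PREDICATE")
  expect_error(read_ontology(write_lines_tmp("no delimiters here")),
               "malformed")
  expect_error(read_ontology(tempfile()), "cannot read")
})

test_that("indicator-rule loader decodes cues and deduplicates", {
  f <- write_lines_tmp(c(
    "treat:verb:none ->TREATS",
    "treatment:noun:with(subject) ->TREATS",
    "treatment:noun:with(subject) ->TREATS",
    "contribution:noun:to(object) ->AFFECTS",
    "in:prep:none ->LOCATION_OF !inverse",
    "lack:verb:none ->NEG_PROCESS_OF"))
  rules <- read_indicator_rules(f)
  expect_equal(nrow(rules), 5L)  # duplicate collapsed
  tr <- rules[rules$lexeme == "treatment", ]
  expect_equal(tr$cue_role, "subject")
  expect_equal(tr$cue_word, "with")
  expect_equal(tr$predicate, "TREATS")
  expect_true(rules$inverse[rules$lexeme == "in"])
  expect_true(rules$implicit_negative[rules$lexeme == "lack"])
  expect_false(any(rules$implicit_negative[rules$lexeme != "lack"]))

  expect_error(read_indicator_rules(write_lines_tmp("treat:verb:with[bad ->TREATS")),
               "cue")
  expect_error(read_indicator_rules(
    write_lines_tmp("MOD_HEAD:MOD_HEAD:with(subject) ->PROCESS_OF")),
    "cue")
})

test_that("arrow variants in rule files are both accepted", {
  r1 <- read_indicator_rules(write_lines_tmp("treat:verb:none ->TREATS"))
  r2 <- read_indicator_rules(write_lines_tmp("treat:verb:none \u2192TREATS"))
  expect_equal(r1$predicate, r2$predicate)
  expect_equal(r1$lexeme, r2$lexeme)
})

test_that("licensed_orientations reports FORWARD and gated INVERSE", {
  ont <- test_kb$ontology
  expect_equal(licensed_orientations("Disease or Syndrome", "CAUSES",
                                     "Disease or Syndrome", ont), "FORWARD")
  expect_equal(licensed_orientations("Anything", "TREATS", "Whatever",
                                     data.frame(subject_type = character(),
                                                predicate = character(),
                                                object_type = character())),
               character())
  # brute-force oracle over the bundled ontology table: is the transposed
  # triple present?
  inv_expected <- any(ont$predicate == "LOCATION_OF" &
                        ont$subject_type == "Body Part, Organ, or Organ Component" &
                        ont$object_type == "Disease or Syndrome")
  got <- licensed_orientations("Disease or Syndrome", "LOCATION_OF",
                               "Body Part, Organ, or Organ Component",
                               ont, allow_inverse = TRUE)
  expect_equal("INVERSE" %in% got, inv_expected)
  expect_false("FORWARD" %in% got)
  # without the inverse capability the orientation is not reported
  expect_equal(licensed_orientations("Disease or Syndrome", "LOCATION_OF",
                                     "Body Part, Organ, or Organ Component",
                                     ont, allow_inverse = FALSE), character())
})

test_that("dysonym rule: substring suppression with exception terms and explicit list", {
  expect_true(is_dysonym("influenza", "Influenza virus vaccine",
                         exception_terms = c("procedure", "disorder", "gene")))
  expect_false(is_dysonym("influenza", "Influenza"))
  expect_false(is_dysonym("X", "X (procedure)",
                          exception_terms = c("procedure", "disorder", "gene")))
  expl <- data.frame(surface = "best", id = "C0339510", stringsAsFactors = FALSE)
  expect_true(is_dysonym("best", "Vitelliform dystrophy",
                         explicit_list = expl, concept_id = "C0339510"))
  expect_false(is_dysonym("best", "Vitelliform dystrophy",
                          explicit_list = expl, concept_id = "C9999999"))
  # word-level containment: an inflected near-match is not a substring
  expect_false(is_dysonym("hip fracture", "Hip Fractures"))
})

test_that("domain extension application blocks, recontextualizes, and merges", {
  kb2 <- apply_domain_extension(test_kb, test_kb$extensions$disaster)
  # blocked mapping: "board" no longer reaches C0972401
  s <- annotate_sentence("The board was convened.", kb2)
  ids <- unlist(lapply(s$phrases, function(p)
    vapply(p$mappings, `[[`, "", "concept_id")))
  expect_false("C0972401" %in% ids)
  s0 <- annotate_sentence("The board was convened.", test_kb)
  ids0 <- unlist(lapply(s0$phrases, function(p)
    vapply(p$mappings, `[[`, "", "concept_id")))
  expect_true("C0972401" %in% ids0)
  # recontextualization: Death Rate moves to the domain semantic type
  expect_equal(concept_types(kb2, "C0205848"), "Community Characteristics")
  expect_equal(concept_types(test_kb, "C0205848"), "Quantitative Concept")
  # new concept and domain rules merged; original untouched
  expect_true("D0000233" %in% kb2$concepts$id)
  expect_false("D0000233" %in% test_kb$concepts$id)
  expect_true("ALERTS" %in% kb2$rules$predicate)
  # empty extension leaves the knowledge base semantically identical
  empty <- as_domain_extension(list(name = "empty"))
  kb3 <- apply_domain_extension(test_kb, empty)
  expect_equal(kb3$concepts, test_kb$concepts)
  expect_equal(kb3$ontology, test_kb$ontology)
  # invalid references are rejected
  bad <- as_domain_extension(list(name = "bad", recontextualizations = list(
    list(id = "C404", old_type = "Finding", new_type = "Human"))))
  expect_error(apply_domain_extension(test_kb, bad), "unknown concept")
})

test_that("fixture bundle is deterministic and serializes round-trip", {
  kb_a <- build_fixture_kb()
  kb_b <- build_fixture_kb()
  d1 <- file.path(tempdir(), "kb_a"); d2 <- file.path(tempdir(), "kb_b")
  write_kb(kb_a, d1); write_kb(kb_b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  kb_rt <- read_kb(d1)
  expect_setequal(
    paste(kb_rt$ontology$subject_type, kb_rt$ontology$predicate,
          kb_rt$ontology$object_type),
    paste(kb_a$ontology$subject_type, kb_a$ontology$predicate,
          kb_a$ontology$object_type))
  expect_setequal(format_indicator_rules(kb_rt$rules),
                  format_indicator_rules(kb_a$rules))
  expect_setequal(kb_rt$concepts$id, kb_a$concepts$id)
  expect_setequal(paste(kb_rt$hierarchy$child, kb_rt$hierarchy$parent),
                  paste(kb_a$hierarchy$child, kb_a$hierarchy$parent))
  # the round-tripped bundle drives the pipeline identically
  expect_identical(
    write_simplified(run_pipeline(worked_examples()[[1]]$text, kb_rt)),
    write_simplified(run_pipeline(worked_examples()[[1]]$text, kb_a)))
})

test_that("hierarchy validation rejects cycles; ancestor query is strict", {
  expect_true(is_ancestor(test_kb, "C0013227", "C1000018"))
  expect_false(is_ancestor(test_kb, "C1000018", "C0013227"))
  expect_false(is_ancestor(test_kb, "C0013227", "C0013227"))
  tab <- fixture_concept_table <- test_kb$concepts
  expect_error(predication_kb(
    concepts = test_kb$concepts, synonyms = test_kb$synonyms,
    semgroups = test_kb$semgroups,
    hierarchy = data.frame(child = c("A", "B"), parent = c("B", "A")),
    ontology = test_kb$ontology, rules = test_kb$rules), "cycle")
})

test_that("licensing-closure warning fires for rules without ontology support", {
  rules <- read_indicator_rules(write_lines_tmp("convert:verb:none ->CONVERTS_TO"))
  expect_warning(predication_kb(
    concepts = test_kb$concepts, synonyms = test_kb$synonyms,
    semgroups = test_kb$semgroups, hierarchy = test_kb$hierarchy,
    ontology = test_kb$ontology, rules = rules), "CONVERTS_TO")
})

test_that("inference-rule loader enforces bound conclusion variables", {
  r <- read_inference_rules(write_lines_tmp(
    "IF <X-TREATS-Y AND Z-PROCESS_OF-Y> THEN <X-TREATS-Z>"))
  expect_equal(r$cp, "TREATS")
  expect_equal(r$cs, "X")
  expect_error(read_inference_rules(write_lines_tmp(
    "IF <X-TREATS-Y AND Z-PROCESS_OF-Y> THEN <X-TREATS-Q>")), "not bound")
})

test_that("synthetic reference resources carry the documented count profile", {
  dir <- file.path(tempdir(), "synref")
  paths <- write_synthetic_reference_kb(dir)
  # independent oracle: line-by-line recount of the raw files
  expect_equal(length(readLines(paths$semnet)), 3100L)
  expect_equal(length(readLines(paths$supplementary)), 4298L)
  expect_equal(length(readLines(paths$rules)), 1366L)
  ont <- rbind(read_ontology(paths$semnet, source = "SEMANTIC_NETWORK"),
               read_ontology(paths$supplementary))
  expect_equal(nrow(ont), 7398L)
  rules <- read_indicator_rules(paths$rules)
  expect_equal(nrow(rules), 1366L)
  # per-predicate counts equal a brute-force recount of the source file
  raw_preds <- sub(".*->", "", readLines(paths$rules))
  expect_equal(as.vector(table(rules$predicate)[sort(unique(raw_preds))]),
               as.vector(table(raw_preds)[sort(unique(raw_preds))]))
  # deterministic regeneration
  dir2 <- file.path(tempdir(), "synref2")
  paths2 <- write_synthetic_reference_kb(dir2)
  expect_identical(readLines(paths$rules), readLines(paths2$rules))
})
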