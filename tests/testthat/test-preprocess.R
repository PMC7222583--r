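# Pre-linguistic analysis: MEDLINE parsing, sentence splitting,
# tokenization, abbreviation detection.

test_that("MEDLINE records parse into documents with joined continuations", {
  txt <- paste(
    "PMID- 12975721",
    "TI  - A title about urinary",
    "      tract infection.",
    "AB  - Pyelonephritis was studied.",
    "      Results are reported.",
    sep = "\n")
  docs <- parse_medline(txt)
  expect_length(docs, 1L)
  expect_equal(docs[[1]]$pmid, "12975721")
  expect_equal(docs[[1]]$title, "A title about urinary tract infection.")
  expect_equal(docs[[1]]$abstract,
               "Pyelonephritis was studied. Results are reported.")
  expect_length(parse_medline(""), 0L)
})

test_that("two concatenated MEDLINE records yield two documents in order", {
  txt <- paste(
    "PMID- 111", "TI  - First title.", "AB  - First abstract.",
    "PMID- 222", "TI  - Second title.", "AB  - Second abstract.", sep = "\n")
  docs <- parse_medline(txt)
  expect_length(docs, 2L)
  expect_equal(vapply(docs, `[[`, "", "pmid"), c("111", "222"))
  expect_equal(docs[[2]]$abstract, "Second abstract.")
})

test_that("plain text input becomes one document with empty pmid and title", {
  docs <- parse_medline("Aspirin treats headache.")
  expect_length(docs, 1L)
  expect_equal(docs[[1]]$pmid, "")
  expect_equal(docs[[1]]$title, "")
  expect_equal(docs[[1]]$raw_text, "Aspirin treats headache.")
  expect_error(parse_medline("PMID- 1\nbroken line without field"),
               "unparseable")
})

test_that("sentence splitting respects offsets, titles, and abbreviations", {
  s <- split_sentences("A is B. C is D.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("A is B.", "C is D."))
  # abbreviation guard keeps "approx. 5 mg" inside one sentence
  s2 <- split_sentences("The dose was approx. 5 mg daily. Outcomes improved.")
  expect_equal(nrow(s2), 2L)
  expect_match(s2$text[1], "approx. 5 mg daily", fixed = TRUE)
  expect_equal(nrow(split_sentences("")), 0L)
  doc <- parse_medline("PMID- 1\nTI  - The title.\nAB  - One. Two.")[[1]]
  s3 <- split_sentences(doc)
  expect_equal(s3$section, c("TITLE", "ABSTRACT", "ABSTRACT"))
  # offset fidelity into raw_text
  expect_equal(substring(doc$raw_text, s3$start + 1L, s3$end), s3$text)
})

test_that("tokenizer isolates hyphens and parentheses and preserves offsets", {
  tk <- tokenize("beta1-adrenergic receptor (beta1AR)")
  expect_equal(tk$text,
               c("beta1", "-", "adrenergic", "receptor", "(", "beta1AR", ")"))
  expect_equal(tokenize("aspirin")$text, "aspirin")
  expect_equal(tokenize("non-diabetic patients")$text,
               c("non", "-", "diabetic", "patients"))
  sent <- "MRI revealed a lacunar infarction, untreated."
  tk2 <- tokenize(sent)
  expect_equal(substring(sent, tk2$start + 1L, tk2$end), tk2$text)
  expect_true(tk2$is_punct[tk2$text == ","])
  # idempotence: re-tokenizing the covered text reproduces the tokens
  expect_equal(tokenize(sent)$text, tk2$text)
})

test_that("abbreviation detection follows short/long form matching", {
  ab <- detect_abbreviations("beta1-adrenergic receptor (beta1AR) was cloned.")
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$short, "beta1AR")
  expect_equal(ab$long, "beta1-adrenergic receptor")
  ab2 <- detect_abbreviations("pulmonary arterial hypertension (PAH) is common.")
  expect_equal(ab2$short, "PAH")
  expect_equal(ab2$long, "pulmonary arterial hypertension")
  expect_equal(nrow(detect_abbreviations("No parentheses here.")), 0L)
  # short form must be shorter than its expansion
  expect_true(all(nchar(ab$short) < nchar(ab$long)))
  # mismatched letters are rejected
  expect_equal(nrow(detect_abbreviations("some unrelated words (XYZQ) here.")), 0L)
})

test_that("short forms inherit the long form's concept mappings", {
  # "VBG" is not a dictionary synonym; it maps only through the registered
  # abbreviation pair
  res <- run_one(paste(
    "Vertical banded gastroplasty (VBG) was performed.",
    "VBG reduced weight."))
  for (s in 1:2) {
    ids <- unlist(lapply(res$sentences[[s]]$phrases, function(p)
      vapply(p$mappings, `[[`, "", "concept_id")))
    expect_true("C1000010" %in% ids, info = paste("sentence", s))
  }
  solo <- annotate_one("VBG reduced weight.")
  ids0 <- unlist(lapply(solo$phrases, function(p)
    vapply(p$mappings, `[[`, "", "concept_id")))
  expect_false("C1000010" %in% ids0)
})
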