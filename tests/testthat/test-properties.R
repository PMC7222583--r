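# Property-style invariant suite, run over the bundled worked examples plus
# randomized template sentences under a fixed seed.

property_corpus <- c(vapply(worked_examples(), `[[`, "", "text"),
                     sample_template_sentences(25, seed = 42L))

test_that("licensing soundness: every associative predication is forward-licensed", {
  for (txt in property_corpus) {
    res <- run_one(txt, anaphora = TRUE)
    for (p in res$predications) {
      if (p$predicate %in% c("ISA", "COMPARED_WITH", "HIGHER_THAN",
                             "LOWER_THAN", "SAME_AS")) next
      expect_true("FORWARD" %in% licensed_orientations(
        p$subj$semtypes, p$predicate, p$obj$semtypes, test_kb),
        info = paste(txt, "->", p$subj$name, p$predicate, p$obj$name))
    }
  }
})

test_that("determinism: repeated runs are byte-identical", {
  for (txt in property_corpus[seq(1, length(property_corpus), by = 3)]) {
    a <- run_one(txt, anaphora = TRUE)
    b <- run_one(txt, anaphora = TRUE)
    expect_identical(write_simplified(a), write_simplified(b))
    expect_identical(write_full_fielded(a), write_full_fielded(b))
  }
})

test_that("offset fidelity: every sentence and token span indexes its source", {
  for (txt in property_corpus) {
    doc <- parse_medline(txt)[[1]]
    sents <- split_sentences(doc)
    expect_equal(substring(doc$raw_text, sents$start + 1L, sents$end),
                 sents$text)
    for (stext in sents$text) {
      tk <- tokenize(stext)
      expect_equal(substring(stext, tk$start + 1L, tk$end), tk$text)
    }
  }
})

test_that("negation involution: no double-negative predicate is ever emitted", {
  for (txt in c(property_corpus,
                "The patients did not lack diabetes.",
                "The patients lack diabetes.")) {
    df <- predications(run_one(txt))
    expect_false(any(grepl("^NEG_NEG", df$predicate)))
    # the rendered predicate and the flag agree
    expect_equal(grepl("^NEG_", df$predicate), df$negated)
  }
})

test_that("hypernym constraints: ISA arguments share a group, are hierarchy-related, and avoid excluded groups", {
  for (txt in property_corpus) {
    res <- run_one(txt)
    for (p in res$predications) {
      if (p$predicate != "ISA") next
      gs <- stats::na.omit(semantic_group(test_kb, p$subj$semtypes))
      go <- stats::na.omit(semantic_group(test_kb, p$obj$semtypes))
      shared <- intersect(gs, go)
      expect_gt(length(shared), 0L)
      expect_false(any(c("Anatomy", "Concepts & Ideas") %in% shared))
      expect_true(is_ancestor(test_kb, p$obj$concept_id, p$subj$concept_id))
    }
  }
})

test_that("anaphora specificity: substituted arguments descend from the anaphor concept", {
  ex <- Filter(function(e) e$id == "anaphora_set_membership", worked_examples())[[1]]
  res <- run_one(ex$text, anaphora = TRUE)
  generic <- "C0013227"
  for (p in res$predications) {
    if (p$predicate != "TREATS") next
    expect_true(is_ancestor(test_kb, generic, p$subj$concept_id))
  }
})

test_that("coordination distribution: licensed conjuncts share the argument role", {
  res <- run_one(paste(
    "Cystitis, urethritis and pyelonephritis in cattle most commonly",
    "result from ascending urinary tract infection."))
  df <- predications(res)
  causes <- df[df$predicate == "CAUSES", ]
  conj <- c("Pyelonephritis", "Cystitis", "Urethritis")
  expect_setequal(causes$obj_name, conj)
  expect_equal(unique(causes$subj_name), "Urinary tract infection")
  # conjunct pair compatibility inside emitted coordinations
  for (txt in property_corpus) {
    for (sent in run_one(txt)$sentences) {
      for (co in sent$coordinations) {
        cj <- co$conjuncts
        expect_gte(length(cj), 2L)
        for (i in seq_along(cj)[-1]) {
          expect_true(np_compatible(sent$phrases[[cj[i - 1L]]],
                                    sent$phrases[[cj[i]]],
                                    sent$tokens, sent$tokens, test_kb))
        }
      }
    }
  }
})

test_that("argument reuse: a reused phrase is coordinated, relativized, or pre-PP", {
  for (txt in property_corpus) {
    res <- run_one(txt)
    for (s in seq_along(res$sentences)) {
      sent <- res$sentences[[s]]
      # count only predications from the trigger/argument machinery
      phr_use <- table(unlist(lapply(res$predications, function(p) {
        if (p$sentence != s || p$inferred ||
            p$predicate %in% c("ISA", "COMPARED_WITH", "HIGHER_THAN",
                               "LOWER_THAN", "SAME_AS")) return(NULL)
        c(p$subj_phrase, p$obj_phrase)
      })))
      for (ph in names(phr_use)[phr_use > 1]) {
        q <- as.integer(ph)
        coordinated <- !is.na(coordination_of(sent$coordinations, q))
        last_tok <- sent$phrases[[q]]$last
        nxt_phrase <- next_matching(sent$phrases, q,
                                    function(p) p$kind != "PUNCT")
        pre_pp <- !is.na(nxt_phrase) && sent$phrases[[nxt_phrase]]$kind == "PP"
        pre_rel <- last_tok < nrow(sent$tokens) &&
          tolower(sent$tokens$text[last_tok + 1L]) %in%
            test_kb$word_lists$relativizers
        # modifier-head predications live inside one phrase: the phrase
        # legitimately appears in both roles
        self_contained <- any(vapply(res$predications, function(p) {
          !is.na(p$subj_phrase) && !is.na(p$obj_phrase) &&
            p$sentence == s && p$subj_phrase == q && p$obj_phrase == q
        }, logical(1)))
        # distribution license: the phrase is shared across parallel
        # predications whose other arguments are conjuncts
        other_args <- unlist(lapply(res$predications, function(p) {
          if (p$sentence != s || p$inferred) return(NULL)
          if (identical(p$subj_phrase, q)) return(p$obj_phrase)
          if (identical(p$obj_phrase, q)) return(p$subj_phrase)
          NULL
        }))
        distributed <- any(vapply(sent$coordinations, function(co)
          sum(other_args %in% co$conjuncts) >= 2L, logical(1)))
        expect_true(coordinated || pre_pp || pre_rel || self_contained ||
                      distributed, info = paste(txt, "phrase", q))
      }
    }
  }
})
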