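# Relational analysis: hypernymy, comparatives, trigger detection, argument
# identification, argument reuse, negation, anaphora incorporation,
# inference.

test_that("hypernymy covers all three syntactic manifestations", {
  expect_true("gabapentin|ISA|Anticonvulsants" %in%
                triples_of(run_one("The anticonvulsant gabapentin reduced seizure frequency.")))
  expect_true("Indomethacin|ISA|Anti-Inflammatory Agents, Non-Steroidal" %in%
                triples_of(run_one("Non-steroidal anti-inflammatory drugs such as indomethacin were administered.")))
  expect_true("Modafinil|ISA|Central Nervous System Stimulants" %in%
                triples_of(run_one("Modafinil is a novel stimulant.")))
})

test_that("hypernymy enforces group membership and hierarchy constraints", {
  # two Anatomy concepts in apposition: excluded group, no ISA
  tr <- triples_of(run_one("The internal capsule, the left internal capsule, was affected."))
  expect_false(any(grepl("\\|ISA\\|", tr)))
  # hierarchy-unrelated same-group concepts yield nothing
  tr2 <- triples_of(run_one("The antibiotic ciprofloxacin was given."))
  expect_false(any(grepl("Ciprofloxacin\\|ISA", tr2)))
})

test_that("comparative patterns emit COMPARED_WITH and scaled rankings", {
  tr <- triples_of(run_one(
    "To compare misoprostol with dinoprostone for cervical ripening, women were enrolled."))
  expect_equal(tr, "Misoprostol|COMPARED_WITH|Dinoprostone")

  res <- run_one(paste(
    "Amoxicillin-clavulanate was not as effective as ciprofloxacin",
    "for treating uncomplicated bladder infection."))
  df <- predications(res)
  expect_setequal(df$predicate, c("COMPARED_WITH", "LOWER_THAN"))
  expect_equal(df$scale[df$predicate == "LOWER_THAN"], "EFFECTIVENESS")
  # positive equative reads as SAME_AS on the same scale
  df2 <- predications(run_one(
    "Misoprostol was as effective as dinoprostone for cervical ripening."))
  expect_true("SAME_AS" %in% df2$predicate)
  # no pattern, no comparative output
  expect_length(triples_of(run_one("Aspirin was administered.")), 0L)
})

test_that("trigger detection finds lexical, phrasal, and structural instances", {
  s <- annotate_one("Pyelonephritis in cattle most commonly result from ascending urinary tract infection.")
  inst <- detect_triggers(s, test_kb)
  lexemes <- vapply(inst, function(i) i$rule$lexeme, "")
  expect_true("result" %in% lexemes)
  expect_true("in" %in% lexemes)

  s2 <- annotate_one("Cigarette smoking increased the odds for lung cancer.")
  inst2 <- detect_triggers(s2, test_kb)
  expect_true("{increase,odds}" %in% vapply(inst2, function(i) i$rule$lexeme, ""))

  s3 <- annotate_one("Diabetic patients were enrolled.")
  inst3 <- detect_triggers(s3, test_kb)
  expect_true("MOD_HEAD" %in% vapply(inst3, function(i) i$rule$lexeme, ""))

  # passive flag on BE + past participle
  s4 <- annotate_one("Headache is treated by aspirin.")
  inst4 <- detect_triggers(s4, test_kb)
  tr <- Filter(function(i) i$rule$lexeme == "treat", inst4)[[1]]
  expect_true(tr$passive)
})

test_that("prepositions subcategorized for by the preceding head do not trigger", {
  # lexicon: "reduce" subcategorizes for to/from; craft a kb where "from"
  # also carries an indicator rule, then check the blocked instance
  kb2 <- local({
    kb <- test_kb
    extra <- read_indicator_rules(write_lines_tmp("from:prep:none ->CAUSES"))
    kb$rules <- rbind(kb$rules, extra)
    rebuild_kb_indexes(kb)
  })
  s <- annotate_one("Infection reduced from cystitis treatment.", kb = kb2)
  inst <- detect_triggers(s, kb2)
  from_inst <- Filter(function(i) i$rule$lexeme == "from", inst)
  expect_length(from_inst, 0L)
  # the same preposition does trigger after a non-subcategorizing head
  s2 <- annotate_one("Pyelonephritis results from cystitis.", kb = kb2)
  inst2 <- detect_triggers(s2, kb2)
  expect_length(Filter(function(i) i$rule$lexeme == "from", inst2), 1L)
})

test_that("argument identification binds per indicator class", {
  expect_true("Urinary tract infection|CAUSES|Pyelonephritis" %in% triples_of(
    run_one("Pyelonephritis in cattle most commonly result from ascending urinary tract infection.")))
  expect_true("Stem cells|AFFECTS|Wound healing" %in% triples_of(
    run_one("We studied the contribution of stem cells to kidney repair.")))
  expect_true("ERBB2 Gene|AFFECTS|Tumorigenesis" %in% triples_of(
    run_one("ErbB2-mediated tumorigenesis was studied.")))
  expect_true("Vertical-Banded Gastroplasty|TREATS|Obesity, Morbid" %in% triples_of(
    run_one("Vertical banded gastroplasty for morbid obesity was performed.")))
  # passive voice swaps the argument order
  expect_true("Aspirin|TREATS|Headache" %in% triples_of(
    run_one("Headache is treated by aspirin.")))
  # failure to bind yields no predication rather than an error
  expect_length(triples_of(run_one("Treatment was discussed.")), 0L)
})

test_that("nominal cued-subject pattern binds through the with-phrase", {
  expect_true("Aspirin|TREATS|Headache" %in% triples_of(
    run_one("The treatment of headache with aspirin was effective.")))
})

test_that("argument reuse is blocked without license and distributed over coordination", {
  res <- run_one(paste(
    "Cystitis, urethritis and pyelonephritis in cattle most commonly",
    "result from ascending urinary tract infection."))
  tr <- triples_of(res)
  expect_true(all(c(
    "Urinary tract infection|CAUSES|Pyelonephritis",
    "Urinary tract infection|CAUSES|Cystitis",
    "Urinary tract infection|CAUSES|Urethritis",
    "Pyelonephritis|PROCESS_OF|Cattle") %in% tr))
  # no coordination, no relative: single predication, no expansion
  res2 <- run_one("Aspirin treats headache.")
  expect_equal(triples_of(res2), "Aspirin|TREATS|Headache")
  # an NP bound once is unavailable to a later indicator without license
  res3 <- run_one("Aspirin treats headache for morbid obesity.")
  tr3 <- triples_of(res3)
  expect_false("Aspirin|TREATS|Obesity, Morbid" %in% tr3)
})

test_that("subject and object of one predication may not be co-conjuncts", {
  res <- run_one("Cystitis and pyelonephritis were treated.")
  tr <- triples_of(res)
  expect_false(any(grepl("Cystitis\\|[A-Z_]+\\|Pyelonephritis", tr)))
  expect_false(any(grepl("Pyelonephritis\\|[A-Z_]+\\|Cystitis", tr)))
})

test_that("negation machinery covers arguments, scope, prefixes, and involution", {
  expect_equal(triples_of(run_one(
    "Overnight incubation with 1 microM safrole did not alter cell proliferation.")),
    "Safrole|NEG_AFFECTS|Cell Proliferation")
  expect_equal(triples_of(run_one("Non-diabetic patients were enrolled.")),
               "Diabetes|NEG_PROCESS_OF|Patients")
  expect_equal(triples_of(run_one("Diabetic patients were enrolled.")),
               "Diabetes|PROCESS_OF|Patients")
  # implicit negative + textual negation = positive
  expect_equal(triples_of(run_one("The patients did not lack diabetes.")),
               "Diabetes|PROCESS_OF|Patients")
  expect_equal(triples_of(run_one("The patients lack diabetes.")),
               "Diabetes|NEG_PROCESS_OF|Patients")
  # out-of-scope trigger (intervening non-verbal material) does not negate
  expect_equal(triples_of(run_one("No data exist; aspirin treats headache.")),
               "Aspirin|TREATS|Headache")
})

test_that("anaphora substitution replaces arguments and respects licensing", {
  ex <- Filter(function(e) e$id == "anaphora_set_membership", worked_examples())[[1]]
  before <- predications(run_one(ex$text))
  expect_equal(sum(before$predicate == "TREATS"), 1L)
  expect_equal(before$subj_name[before$predicate == "TREATS"],
               "Pharmaceutical Preparations")
  after <- predications(run_one(ex$text, anaphora = TRUE))
  expect_setequal(after$subj_name[after$predicate == "TREATS"],
                  c("Epoprostenol", "Endothelin receptor antagonist",
                    "Phosphodiesterase 5 inhibitor"))
  # substituted predications carry both sentence ids
  expect_true(all(after$sentence2[after$predicate == "TREATS"] == 1L))
  expect_true(all(after$sentence[after$predicate == "TREATS"] == 2L))
})

test_that("substitution violating licensing keeps the original predication", {
  # antecedent whose semantic type is unlicensed for TREATS: the original
  # generic predication must survive
  kb2 <- local({
    kb <- test_kb
    kb$hierarchy <- rbind(kb$hierarchy,
      data.frame(child = "C1000009", parent = "C0013227"))  # cattle under drugs
    rebuild_kb_indexes(kb)
  })
  res <- run_pipeline(paste(
    "Cows were examined.",
    "These drugs for morbid obesity were discussed."), kb2,
    run_options(anaphora = TRUE))
  df <- predications(res)
  treats <- df[df$predicate == "TREATS", ]
  expect_equal(treats$subj_name, "Pharmaceutical Preparations")
})

test_that("inference reaches a deduplicated fixpoint and flags conclusions", {
  res <- run_one("Replacement arthroplasty for adults with an extracapsular hip fracture was assessed.")
  df <- predications(res)
  inf <- df[df$inferred, ]
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$subj_name, "Arthroplasty, Replacement")
  expect_equal(inf$predicate, "TREATS")
  expect_equal(inf$obj_name, "Hip Fractures")
  expect_equal(inf$indicator_type, "inference")
  expect_false(any(duplicated(paste(df$subj_id, df$predicate, df$obj_id, df$inferred))))
  # no premise match, no additions
  df2 <- predications(run_one("Aspirin treats headache."))
  expect_false(any(df2$inferred))
  # independent oracle: brute-force closure over the non-inferred set
  base <- df[!df$inferred, c("subj_id", "predicate", "obj_id")]
  closure <- base
  repeat {
    new <- NULL
    for (i in seq_len(nrow(closure))) {
      for (j in seq_len(nrow(closure))) {
        if (closure$predicate[i] == "TREATS" &&
            closure$predicate[j] == "PROCESS_OF" &&
            closure$obj_id[i] == closure$obj_id[j]) {
          cand <- data.frame(subj_id = closure$subj_id[i], predicate = "TREATS",
                             obj_id = closure$subj_id[j])
          key <- paste(cand$subj_id, cand$predicate, cand$obj_id)
          have <- paste(closure$subj_id, closure$predicate, closure$obj_id)
          if (!key %in% have) new <- rbind(new, cand)
        }
      }
    }
    if (is.null(new)) break
    closure <- rbind(closure, unique(new))
  }
  derived <- setdiff(paste(closure$subj_id, closure$predicate, closure$obj_id),
                     paste(base$subj_id, base$predicate, base$obj_id))
  expect_setequal(paste(inf$subj_id, inf$predicate, inf$obj_id), derived)
})
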