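# The bundled regression corpus: worked examples exercising every stage of
# the pipeline, each with the predications the bundled knowledge base is
# expected to yield. `expected` lists triples as "Subject|PREDICATE|Object"
# using preferred concept names (NEG_ prefix marks negation, "(infer)"
# marks inferred conclusions); `exact` states whether the expectation is
# the complete output or a required subset.

#' Bundled worked-example regression corpus
#'
#' @return list of examples; each has `id`, `text`, `options` (list passed
#'   to [run_options()]), `expected` (character vector of
#'   `Subject|PREDICATE|Object` triples by preferred name), and `exact`
#'   (is `expected` the complete predication set?).
#' @export
worked_examples <- function() {
  list(
    list(id = "diagnosis_location", exact = TRUE,
         text = "MRI revealed a lacunar infarction in the left internal capsule.",
         expected = c(
           "Magnetic Resonance Imaging|DIAGNOSES|Infarction, Lacunar",
           "Left internal capsule|LOCATION_OF|Infarction, Lacunar")),
    list(id = "comparative_stated", exact = TRUE,
         text = "To compare misoprostol with dinoprostone for cervical ripening, women were enrolled.",
         expected = "Misoprostol|COMPARED_WITH|Dinoprostone"),
    list(id = "comparative_scaled", exact = TRUE,
         text = "Amoxicillin-clavulanate was not as effective as ciprofloxacin for treating uncomplicated bladder infection.",
         expected = c(
           "Amoxicillin-Potassium Clavulanate Combination|COMPARED_WITH|Ciprofloxacin",
           "Amoxicillin-Potassium Clavulanate Combination|LOWER_THAN|Ciprofloxacin")),
    list(id = "verbal_cued_subject", exact = FALSE,
         text = "Pyelonephritis in cattle most commonly result from ascending urinary tract infection.",
         expected = "Urinary tract infection|CAUSES|Pyelonephritis"),
    list(id = "prepositional_treats", exact = FALSE,
         text = "Vertical banded gastroplasty for morbid obesity was performed.",
         expected = "Vertical-Banded Gastroplasty|TREATS|Obesity, Morbid"),
    list(id = "nominal_cued_object", exact = FALSE,
         text = "We studied the contribution of stem cells to kidney repair.",
         expected = "Stem cells|AFFECTS|Wound healing"),
    list(id = "adjectival_hyphenated", exact = FALSE,
         text = "ErbB2-mediated tumorigenesis was studied.",
         expected = "ERBB2 Gene|AFFECTS|Tumorigenesis"),
    list(id = "coordination_argument_reuse", exact = FALSE,
         text = "Cystitis, urethritis and pyelonephritis in cattle most commonly result from ascending urinary tract infection.",
         expected = c(
           "Urinary tract infection|CAUSES|Pyelonephritis",
           "Urinary tract infection|CAUSES|Cystitis",
           "Urinary tract infection|CAUSES|Urethritis")),
    list(id = "reduced_relative_process_of", exact = FALSE,
         text = "Cystitis, urethritis and pyelonephritis in cattle most commonly result from ascending urinary tract infection.",
         expected = "Pyelonephritis|PROCESS_OF|Cattle"),
    list(id = "verbal_negation", exact = TRUE,
         text = "Overnight incubation with 1 microM safrole did not alter cell proliferation.",
         expected = "Safrole|NEG_AFFECTS|Cell Proliferation"),
    list(id = "anaphora_set_membership", exact = FALSE,
         options = list(anaphora = TRUE),
         text = paste(
           "There are currently 3 classes of drugs approved for the treatment of PAH:",
           "prostacyclin analogues, endothelin receptor antagonists, and",
           "phosphodiesterase type 5 inhibitors.",
           "The current evidence supports the long-term use of these drugs",
           "for the treatment of patients with PAH."),
         expected = c(
           "Epoprostenol|TREATS|Pulmonary arterial hypertension",
           "Endothelin receptor antagonist|TREATS|Pulmonary arterial hypertension",
           "Phosphodiesterase 5 inhibitor|TREATS|Pulmonary arterial hypertension")),
    list(id = "inference_treats", exact = FALSE,
         text = "Replacement arthroplasty for adults with an extracapsular hip fracture was assessed.",
         expected = c(
           "Hip Fractures|PROCESS_OF|Adult",
           "Arthroplasty, Replacement|TREATS|Adult",
           "Arthroplasty, Replacement|TREATS(infer)|Hip Fractures")),
    list(id = "hypernym_modifier_head", exact = FALSE,
         text = "The anticonvulsant gabapentin reduced seizure frequency.",
         expected = "gabapentin|ISA|Anticonvulsants"),
    list(id = "hypernym_such_as", exact = FALSE,
         text = "Non-steroidal anti-inflammatory drugs such as indomethacin were administered.",
         expected = "Indomethacin|ISA|Anti-Inflammatory Agents, Non-Steroidal"),
    list(id = "hypernym_verbal_be", exact = FALSE,
         text = "Modafinil is a novel stimulant.",
         expected = "Modafinil|ISA|Central Nervous System Stimulants"),
    list(id = "mod_head_negation", exact = TRUE,
         text = "Non-diabetic patients were enrolled.",
         expected = "Diabetes|NEG_PROCESS_OF|Patients"),
    list(id = "implicit_negative_flip", exact = TRUE,
         text = "The patients did not lack diabetes.",
         expected = "Diabetes|PROCESS_OF|Patients")
  )
}

render_triple <- function(p) {
  pred <- if (p$negated) paste0("NEG_", p$predicate) else p$predicate
  if (p$inferred) pred <- paste0(pred, "(infer)")
  paste(p$subj$name, pred, p$obj$name, sep = "|")
}

#' Run the worked-example regression corpus
#'
#' Runs the pipeline over every bundled worked example and compares the
#' extracted triples (by preferred name) with the expectations.
#'
#' @param kb a `predication_kb` (default: the bundled fixture bundle).
#' @return data.frame with one row per example: `id`, `n_expected`,
#'   `n_found`, `n_extracted`, `pass`.
#' @export
check_worked_examples <- function(kb = fixture_kb()) {
  rows <- lapply(worked_examples(), function(ex) {
    opts <- do.call(run_options, ex$options %||% list())
    res <- run_pipeline(ex$text, kb, opts)
    triples <- vapply(res$predications, render_triple, "")
    found <- ex$expected %in% triples
    pass <- all(found) && (!isTRUE(ex$exact) ||
                             setequal(triples, ex$expected))
    data.frame(id = ex$id, n_expected = length(ex$expected),
               n_found = sum(found), n_extracted = length(triples),
               pass = pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
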