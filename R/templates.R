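# Template sentence generator for property-style testing. The templates
# instantiate the argument structures the pipeline handles (verbal,
# prepositional, nominal, coordination, negation, comparatives) with
# concept synonyms drawn from the bundled knowledge base, so invariants can
# be checked over randomized but well-formed inputs.

template_slot_fillers <- function() {
  list(
    DRUG = c("aspirin", "cetirizine", "gabapentin", "misoprostol",
             "dinoprostone", "ciprofloxacin", "modafinil", "indomethacin"),
    DISEASE = c("influenza", "pyelonephritis", "cystitis", "urethritis",
                "morbid obesity", "pulmonary arterial hypertension",
                "lacunar infarction", "infection"),
    DISEASE2 = c("urinary tract infection", "diabetes", "infection"),
    CANCER = c("osteosarcoma", "melanoma", "breast cancer", "lung cancer"),
    CHEM = c("safrole"),
    FUNC = c("cell proliferation"),
    GROUP = c("adults", "patients")
  )
}

template_sentences <- function() {
  c("%DRUG% treats %DISEASE%.",
    "%DISEASE% in cattle most commonly result from ascending %DISEASE2%.",
    "%CANCER%, %CANCER% and %CANCER% were observed.",
    "Overnight incubation with %CHEM% did not alter %FUNC%.",
    "%DRUG% was not as effective as %DRUG% for treating %DISEASE%.",
    "%DRUG% is used for %DISEASE%.",
    "%DISEASE% was diagnosed in %GROUP%.",
    "The anticonvulsant %DRUG% was administered to %GROUP%.",
    "%DRUG% did not treat %DISEASE%.")
}

#' Sample randomized template sentences
#'
#' Draws sentences from a fixed template inventory, filling slots with
#' concept synonyms from the bundled knowledge base. Deterministic for a
#' given seed.
#'
#' @param n number of sentences.
#' @param seed integer seed.
#' @return character vector of sentences.
#' @export
sample_template_sentences <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    templates <- template_sentences()
    fillers <- template_slot_fillers()
    vapply(seq_len(n), function(i) {
      s <- sample(templates, 1L)
      repeat {
        m <- regmatches(s, regexec("%([A-Z0-9]+)%", s))[[1]]
        if (length(m) < 2) break
        slot <- m[2]
        s <- sub(paste0("%", slot, "%"), sample(fillers[[slot]], 1L), s)
      }
      # sentence-initial capitalization
      sub("^([a-z])", "\\U\\1", s, perl = TRUE)
    }, "")
  })
  rng
}
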