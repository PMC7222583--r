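# The bundled miniature knowledge base. It emulates the role of a full
# terminology (Metathesaurus-like dictionary, semantic-type network,
# concept hierarchy, indicator rules) at fixture scale: it covers exactly
# the concepts, types, and rules needed by the worked examples that ship
# with the package. Concept ids without an authoritative printed source are
# synthetic (C1xxxxxx series); the bundle as a whole is a synthetic
# miniature, not an extract of any licensed terminology.

fixture_semgroups <- function() {
  g <- c(
    "Diagnostic Procedure" = "Procedures",
    "Therapeutic or Preventive Procedure" = "Procedures",
    "Laboratory Procedure" = "Procedures",
    "Disease or Syndrome" = "Disorders",
    "Neoplastic Process" = "Disorders",
    "Sign or Symptom" = "Disorders",
    "Finding" = "Disorders",
    "Body Part, Organ, or Organ Component" = "Anatomy",
    "Cell" = "Anatomy",
    "Pharmacologic Substance" = "Chemicals & Drugs",
    "Organic Chemical" = "Chemicals & Drugs",
    "Antibiotic" = "Chemicals & Drugs",
    "Gene or Genome" = "Genes & Molecular Sequences",
    "Cell Function" = "Physiology",
    "Organism Function" = "Physiology",
    "Organ or Tissue Function" = "Physiology",
    "Mammal" = "Living Beings",
    "Patient or Disabled Group" = "Living Beings",
    "Age Group" = "Living Beings",
    "Population Group" = "Living Beings",
    "Human" = "Living Beings",
    "Individual Behavior" = "Behaviors",
    "Medical Device" = "Devices",
    "Qualitative Concept" = "Concepts & Ideas",
    "Quantitative Concept" = "Concepts & Ideas",
    "Functional Concept" = "Concepts & Ideas",
    "Temporal Concept" = "Concepts & Ideas",
    "Idea or Concept" = "Concepts & Ideas",
    "Information Construct" = "Concepts & Ideas"
  )
  data.frame(type = names(g), group = unname(g), stringsAsFactors = FALSE)
}

# id | preferred name | semtypes | synonyms (|-separated) | source
fixture_concept_table <- function() {
  rows <- list(
    list("C0024485", "Magnetic Resonance Imaging", "Diagnostic Procedure",
         "magnetic resonance imaging|mri"),
    list("C0333559", "Infarction, Lacunar", "Disease or Syndrome",
         "lacunar infarction|lacunar infarctions"),
    list("C2339807", "Left internal capsule", "Body Part, Organ, or Organ Component",
         "left internal capsule"),
    list("C1000090", "Internal capsule", "Body Part, Organ, or Organ Component",
         "internal capsule"),
    list("C0021400", "Influenza", "Disease or Syndrome", "influenza|flu"),
    list("C0021403", "Influenza virus vaccine", "Pharmacologic Substance",
         "influenza|influenza virus vaccine|flu vaccine"),
    list("C1538308", "ATXN10 gene", "Gene or Genome", "ataxin-10|atxn10 gene"),
    list("C0812225", "ERBB2 Gene", "Gene or Genome", "erbb2|erbb2 gene|her2"),
    list("C1000091", "CYP2C9 gene", "Gene or Genome", "cyp2c9"),
    list("C0339510", "Vitelliform dystrophy", "Disease or Syndrome",
         "best|vitelliform dystrophy"),
    list("C0309050", "FAVOR", "Pharmacologic Substance", "favor"),
    list("C0972401", "Boards", "Medical Device", "board|boards"),
    list("C0205848", "Death Rate", "Quantitative Concept", "death rate"),
    list("C0337664", "Smoker", "Finding", "smoker|smokers"),
    list("C0013227", "Pharmaceutical Preparations", "Pharmacologic Substance",
         "drug|drugs|pharmaceutical preparations|medication|medications"),
    list("C1000001", "Misoprostol", "Pharmacologic Substance", "misoprostol"),
    list("C1000002", "Dinoprostone", "Pharmacologic Substance", "dinoprostone"),
    list("C1000003", "Amoxicillin-Potassium Clavulanate Combination", "Antibiotic",
         "amoxicillin-clavulanate|amoxicillin-potassium clavulanate combination"),
    list("C1000004", "Ciprofloxacin", "Antibiotic", "ciprofloxacin"),
    list("C1000005", "Urinary tract infection", "Disease or Syndrome",
         "urinary tract infection|urinary tract infections"),
    list("C1000006", "Pyelonephritis", "Disease or Syndrome", "pyelonephritis"),
    list("C1000007", "Cystitis", "Disease or Syndrome", "cystitis"),
    list("C1000008", "Urethritis", "Disease or Syndrome", "urethritis"),
    list("C1000009", "Cattle", "Mammal", "cattle|cow|cows"),
    list("C1000010", "Vertical-Banded Gastroplasty", "Therapeutic or Preventive Procedure",
         "vertical banded gastroplasty|vertical-banded gastroplasty"),
    list("C1000011", "Obesity, Morbid", "Disease or Syndrome", "morbid obesity"),
    list("C1000012", "Stem cells", "Cell", "stem cells|stem cell"),
    list("C1000013", "Wound healing", "Organism Function",
         "wound healing|kidney repair|tissue repair"),
    list("C1000014", "Tumorigenesis", "Neoplastic Process", "tumorigenesis"),
    list("C1000015", "Safrole", "Organic Chemical", "safrole"),
    list("C1000016", "Cell Proliferation", "Cell Function", "cell proliferation"),
    list("C1000017", "Pulmonary arterial hypertension", "Disease or Syndrome",
         "pulmonary arterial hypertension|pah"),
    list("C1000018", "Epoprostenol", "Pharmacologic Substance",
         "epoprostenol|prostacyclin analogue|prostacyclin analogues"),
    list("C1000019", "Endothelin receptor antagonist", "Pharmacologic Substance",
         "endothelin receptor antagonist|endothelin receptor antagonists"),
    list("C1000020", "Phosphodiesterase 5 inhibitor", "Pharmacologic Substance",
         "phosphodiesterase 5 inhibitor|phosphodiesterase type 5 inhibitors|phosphodiesterase type 5 inhibitor"),
    list("C1000021", "Hip Fractures", "Disease or Syndrome",
         "hip fracture|hip fractures"),
    list("C1000022", "Adult", "Age Group", "adult|adults"),
    list("C1000023", "Arthroplasty, Replacement", "Therapeutic or Preventive Procedure",
         "replacement arthroplasty|arthroplasty"),
    list("C1000024", "gabapentin", "Pharmacologic Substance", "gabapentin"),
    list("C1000025", "Anticonvulsants", "Pharmacologic Substance",
         "anticonvulsant|anticonvulsants"),
    list("C1000026", "Diabetes", "Disease or Syndrome", "diabetes|diabetic"),
    list("C1000027", "Patients", "Patient or Disabled Group", "patient|patients"),
    list("C1000028", "Cetirizine", "Pharmacologic Substance", "cetirizine"),
    list("C1000029", "Genes", "Gene or Genome", "gene|genes"),
    list("C1000030", "BRCA1 gene", "Gene or Genome", "brca1"),
    list("C1000031", "Osteosarcoma", "Neoplastic Process", "osteosarcoma"),
    list("C1000032", "Melanoma", "Neoplastic Process", "melanoma"),
    list("C1000033", "Breast Carcinoma", "Neoplastic Process",
         "breast cancer|breast carcinoma"),
    list("C1000034", "Lung Neoplasms", "Neoplastic Process", "lung cancer|lung neoplasms"),
    list("C1000035", "Smoking", "Individual Behavior", "smoking|cigarette smoking"),
    list("C1000036", "Modafinil", "Pharmacologic Substance", "modafinil"),
    list("C1000037", "Central Nervous System Stimulants", "Pharmacologic Substance",
         "stimulant|stimulants|central nervous system stimulants"),
    list("C1000038", "Anti-Inflammatory Agents, Non-Steroidal", "Pharmacologic Substance",
         "nsaid|nsaids|non-steroidal anti-inflammatory drugs|non-steroidal anti-inflammatory drug"),
    list("C1000039", "Indomethacin", "Pharmacologic Substance", "indomethacin"),
    list("C1000040", "Variant", "Qualitative Concept", "variant|variants"),
    list("C1000041", "Concentration", "Quantitative Concept", "concentration"),
    list("C1000042", "Headache", "Sign or Symptom", "headache|headaches"),
    list("C1000043", "Aspirin", "Pharmacologic Substance", "aspirin"),
    list("C1000044", "Infection", "Disease or Syndrome", "infection|infections"),
    list("C1000045", "beta1-adrenergic receptor", "Gene or Genome",
         "beta1-adrenergic receptor"),
    list("C1000046", "Seizures", "Disease or Syndrome", "seizure|seizures|clonic seizures")
  )
  data.frame(
    id = vapply(rows, `[[`, "", 1), name = vapply(rows, `[[`, "", 2),
    semtypes = vapply(rows, `[[`, "", 3), synonyms = vapply(rows, `[[`, "", 4),
    stringsAsFactors = FALSE)
}

fixture_hierarchy <- function() {
  edges <- rbind(
    c("C1000024", "C1000025"),  # gabapentin -> Anticonvulsants
    c("C1000039", "C1000038"),  # Indomethacin -> NSAIDs
    c("C1000036", "C1000037"),  # Modafinil -> CNS Stimulants
    c("C1000018", "C0013227"),  # Epoprostenol -> Pharmaceutical Preparations
    c("C1000019", "C0013227"),
    c("C1000020", "C0013227"),
    c("C1000028", "C0013227"),  # Cetirizine -> Pharmaceutical Preparations
    c("C1000043", "C0013227"),
    c("C1000030", "C1000029"),  # BRCA1 -> Genes
    c("C1000091", "C1000029"),
    c("C0812225", "C1000029"),
    c("C1538308", "C1000029"),
    c("C2339807", "C1000090")   # Left internal capsule -> Internal capsule
  )
  data.frame(child = edges[, 1], parent = edges[, 2], stringsAsFactors = FALSE)
}

fixture_ontology <- function() {
  triples <- list(
    # source SEMANTIC_NETWORK for the classical triples, SUPPLEMENTARY for
    # the expansions; the split only matters for provenance statistics.
    c("Diagnostic Procedure", "DIAGNOSES", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Body Part, Organ, or Organ Component", "LOCATION_OF", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Disease or Syndrome", "CAUSES", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Pharmacologic Substance", "TREATS", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Antibiotic", "TREATS", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Pharmacologic Substance", "TREATS", "Sign or Symptom", "SEMANTIC_NETWORK"),
    c("Therapeutic or Preventive Procedure", "TREATS", "Disease or Syndrome", "SEMANTIC_NETWORK"),
    c("Therapeutic or Preventive Procedure", "TREATS", "Age Group", "SUPPLEMENTARY"),
    c("Cell", "AFFECTS", "Organism Function", "SUPPLEMENTARY"),
    c("Gene or Genome", "AFFECTS", "Neoplastic Process", "SUPPLEMENTARY"),
    c("Organic Chemical", "AFFECTS", "Cell Function", "SEMANTIC_NETWORK"),
    c("Disease or Syndrome", "PROCESS_OF", "Mammal", "SEMANTIC_NETWORK"),
    c("Disease or Syndrome", "PROCESS_OF", "Patient or Disabled Group", "SUPPLEMENTARY"),
    c("Disease or Syndrome", "PROCESS_OF", "Age Group", "SUPPLEMENTARY"),
    c("Disease or Syndrome", "PROCESS_OF", "Human", "SEMANTIC_NETWORK"),
    c("Individual Behavior", "PREDISPOSES", "Neoplastic Process", "SUPPLEMENTARY"),
    c("Gene or Genome", "INTERACTS_WITH", "Gene or Genome", "SUPPLEMENTARY"),
    c("Pharmacologic Substance", "INTERACTS_WITH", "Pharmacologic Substance", "SEMANTIC_NETWORK")
  )
  data.frame(
    subject_type = vapply(triples, `[`, "", 1),
    predicate = vapply(triples, `[`, "", 2),
    object_type = vapply(triples, `[`, "", 3),
    source = vapply(triples, `[`, "", 4), stringsAsFactors = FALSE)
}

fixture_rule_lines <- function() {
  c(
    "treat:verb:none ->TREATS",
    "treatment:noun:with(subject) ->TREATS",
    "therapy:noun:with(subject) ->TREATS",
    "for:prep:none ->TREATS",
    "result:verb:from(subject) ->CAUSES",
    "reveal:verb:none ->DIAGNOSES",
    "in:prep:none ->LOCATION_OF !inverse",
    "in:prep:none ->PROCESS_OF",
    "with:prep:none ->PROCESS_OF !inverse",
    "alter:verb:none ->AFFECTS",
    "affect:verb:none ->AFFECTS",
    "contribution:noun:to(object) ->AFFECTS",
    "mediated:adj:none ->AFFECTS",
    "lack:verb:none ->NEG_PROCESS_OF !inverse",
    "MOD_HEAD:MOD_HEAD:none ->PROCESS_OF",
    "increased risk:noun:for(object) ->PREDISPOSES",
    "{increase,odds}:verb:for(object) ->PREDISPOSES",
    "interact:verb:with(object) ->INTERACTS_WITH"
  )
}

fixture_gene_index <- function() {
  rows <- rbind(
    c("ataxin-10", "25814", "ATXN10"),
    c("atxn10", "25814", "ATXN10"),
    c("ogt", "8473", "OGT"),
    c("o-glcnac transferase", "8473", "OGT"),
    c("erbb2", "2064", "ERBB2"),
    c("her2", "2064", "ERBB2"),
    c("cyp2c9", "1559", "CYP2C9"),
    c("brca1", "672", "BRCA1")
  )
  data.frame(alias = rows[, 1], gene_id = rows[, 2], symbol = rows[, 3],
             stringsAsFactors = FALSE)
}

# surface | base | cat | features
fixture_lexicon_rows <- function() {
  verb <- function(base, forms, feats = "") {
    do.call(rbind, lapply(names(forms), function(f)
      c(f, base, "verb", paste0(forms[[f]], if (nzchar(feats)) paste0(";", feats)))))
  }
  std_verb <- function(base, past = paste0(base, "ed"), s3 = paste0(base, "s"),
                       ing = paste0(sub("e$", "", base), "ing"), feats = "") {
    verb(base, stats::setNames(
      list("", "tense=past;tense=pastpart", "number=s3", "tense=prespart"),
      c(base, past, s3, ing)), feats)
  }
  rows <- rbind(
    std_verb("reduce", "reduced", feats = "subcat=to|from;nominalization=reduction"),
    std_verb("treat", "treated"),
    std_verb("reveal", "revealed"),
    std_verb("result", "resulted"),
    std_verb("compare", "compared"),
    std_verb("alter", "altered"),
    std_verb("affect", "affected"),
    std_verb("lack", "lacked"),
    std_verb("approve", "approved"),
    std_verb("support", "supported"),
    std_verb("increase", "increased"),
    std_verb("mediate", "mediated"),
    std_verb("interact", "interacted"),
    std_verb("remain", "remained"),
    std_verb("enroll", "enrolled"),
    std_verb("administer", "administered"),
    std_verb("observe", "observed"),
    std_verb("diagnose", "diagnosed"),
    std_verb("sequence", "sequenced"),
    std_verb("relieve", "relieved"),
    std_verb("use", "used"),
    std_verb("incubate", "incubated"),
    # BE forms double as auxiliary and verb (disambiguated in context)
    c("be", "be", "verb", "be=1"), c("be", "be", "aux", "be=1"),
    c("is", "be", "verb", "be=1;number=s3"), c("is", "be", "aux", "be=1"),
    c("are", "be", "verb", "be=1"), c("are", "be", "aux", "be=1"),
    c("was", "be", "verb", "be=1;tense=past"), c("was", "be", "aux", "be=1"),
    c("were", "be", "verb", "be=1;tense=past"), c("were", "be", "aux", "be=1"),
    c("been", "be", "verb", "be=1;tense=pastpart"), c("been", "be", "aux", "be=1"),
    c("being", "be", "verb", "be=1"), c("being", "be", "aux", "be=1"),
    c("have", "have", "verb", ""), c("have", "have", "aux", ""),
    c("has", "have", "verb", "number=s3"), c("has", "have", "aux", ""),
    c("had", "have", "verb", "tense=past;tense=pastpart"), c("had", "have", "aux", ""),
    c("do", "do", "aux", ""), c("did", "do", "aux", "tense=past"),
    c("does", "do", "aux", ""),
    # noun homonyms of ambiguous stems
    c("result", "result", "noun", ""), c("results", "result", "noun", "number=plural"),
    c("increase", "increase", "noun", ""), c("increases", "increase", "noun", "number=plural"),
    c("use", "use", "noun", ""), c("lack", "lack", "noun", ""),
    c("treatment", "treatment", "noun", "nominalization_of=treat"),
    c("treatments", "treatment", "noun", "number=plural"),
    c("therapy", "therapy", "noun", ""),
    c("contribution", "contribution", "noun", ""),
    c("comparison", "comparison", "noun", ""),
    c("risk", "risk", "noun", ""), c("risks", "risk", "noun", "number=plural"),
    c("odds", "odds", "noun", "number=plural"),
    c("evidence", "evidence", "noun", ""),
    c("incubation", "incubation", "noun", ""),
    c("calcium antagonists", "calcium antagonist", "noun", "number=plural"),
    c("calcium antagonist", "calcium antagonist", "noun", ""),
    # adjectives and adverbs
    c("effective", "effective", "adj", ""),
    c("efficacious", "efficacious", "adj", ""),
    c("safe", "safe", "adj", ""),
    c("novel", "novel", "adj", ""),
    c("current", "current", "adj", ""),
    c("ascending", "ascending", "adj", ""),
    c("uncomplicated", "uncomplicated", "adj", ""),
    c("long-term", "long-term", "adj", ""),
    c("overnight", "overnight", "adj", ""),
    c("vertical", "vertical", "adj", ""),
    c("morbid", "morbid", "adj", ""),
    c("lacunar", "lacunar", "adj", ""),
    c("extracapsular", "extracapsular", "adj", ""),
    c("not", "not", "adv", ""), c("most", "most", "adv", ""),
    c("commonly", "commonly", "adv", ""), c("currently", "currently", "adv", ""),
    c("there", "there", "adv", ""), c("also", "also", "adv", ""),
    c("only", "only", "adv", ""), c("necessarily", "necessarily", "adv", ""),
    c("more", "more", "adv", ""), c("less", "less", "adv", "")
  )
  rows
}

fixture_lexicon <- function() {
  rows <- fixture_lexicon_rows()
  data.frame(surface = rows[, 1], base = rows[, 2], cat = rows[, 3],
             features = rows[, 4], stringsAsFactors = FALSE)
}

fixture_inference_lines <- function() {
  # only one of the inference rules is part of the seeded inventory; the
  # inventory is configuration, not code.
  "IF <X-TREATS-Y AND Z-PROCESS_OF-Y> THEN <X-TREATS-Z>"
}

fixture_extensions <- function() {
  disaster <- as_domain_extension(list(
    name = "disaster",
    semantic_types = list(list(type = "Community Characteristics", group = "Phenomena")),
    blocked_mappings = list(list(surface = "board", id = "C0972401")),
    recontextualizations = list(list(id = "C0205848",
                                     old_type = "Quantitative Concept",
                                     new_type = "Community Characteristics")),
    concepts = list(list(id = "D0000233", name = "Health Alert Notice",
                         semtypes = list("Information Construct"),
                         synonyms = list("health alert", "health alert notice"))),
    ontology = list("Organization-MONITORS-Virus",
                    "Organization-ALERTS-Population Group"),
    rules = list("caution:verb:none ->ALERTS",
                 "contamination:noun:none ->INFECTS")
  ))
  generic_concepts <- as_domain_extension(list(
    name = "generic_concepts",
    concepts = list(list(id = "G0000211", name = "cancer-free survival",
                         semtypes = list("Organism Function"),
                         synonyms = list("cancer-free survival")))
  ))
  generic_recontext <- as_domain_extension(list(
    name = "generic_recontextualization",
    recontextualizations = list(list(id = "C0337664", old_type = "Finding",
                                     new_type = "Population Group"))
  ))
  list(disaster = disaster, generic_concepts = generic_concepts,
       generic_recontextualization = generic_recontext)
}

#' Build the bundled fixture knowledge base
#'
#' Deterministically constructs the miniature knowledge base that ships with
#' the package: every concept, semantic type, hierarchy edge, ontological
#' predication, indicator rule, lexicon record, and word-list entry needed by
#' the worked examples in the package documentation (diagnosis/location,
#' comparatives, causation with coordination and argument reuse, nominal and
#' adjectival indicators, negation, sortal anaphora, inference), plus the
#' disaster-domain and generic extensions. Building twice yields identical
#' bundles.
#'
#' @return a `predication_kb`.
#' @export
build_fixture_kb <- function() {
  tab <- fixture_concept_table()
  synonyms <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(surface = strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]],
               id = tab$id[i], stringsAsFactors = FALSE)
  }))
  rules_file <- tempfile(); on.exit(unlink(rules_file))
  writeLines(fixture_rule_lines(), rules_file)
  inf_file <- tempfile(fileext = ".txt")
  writeLines(fixture_inference_lines(), inf_file)
  on.exit(unlink(inf_file), add = TRUE)
  wl <- default_word_lists()
  wl$dysonyms <- data.frame(surface = c("best", "favor"),
                            id = c("C0339510", "C0309050"),
                            stringsAsFactors = FALSE)
  predication_kb(
    concepts = data.frame(id = tab$id, name = tab$name, semtypes = tab$semtypes,
                          source = "METATHESAURUS", stringsAsFactors = FALSE),
    synonyms = synonyms,
    semgroups = fixture_semgroups(),
    hierarchy = fixture_hierarchy(),
    ontology = fixture_ontology(),
    rules = read_indicator_rules(rules_file),
    gene_index = fixture_gene_index(),
    lexicon = fixture_lexicon(),
    inference_rules = read_inference_rules(inf_file),
    word_lists = wl,
    extensions = fixture_extensions()
  )
}

fixture_kb_cache <- new.env(parent = emptyenv())

#' Cached fixture knowledge base
#'
#' Memoised accessor for [build_fixture_kb()]; the bundle is immutable, so a
#' single shared copy is safe.
#' @return a `predication_kb`.
#' @export
fixture_kb <- function() {
  if (is.null(fixture_kb_cache$kb)) fixture_kb_cache$kb <- build_fixture_kb()
  fixture_kb_cache$kb
}
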