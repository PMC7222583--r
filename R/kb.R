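#' @keywords internal
"_PACKAGE"

# Closed predicate inventory: the 25 associative predicates, plus ISA and the
# comparative predicates. NEG_ variants are flags on these, not separate
# inventory members (implicit-negative indicator rules excepted).
ASSOCIATIVE_PREDICATES <- c(
  "ADMINISTERED_TO", "AFFECTS", "ASSOCIATED_WITH", "AUGMENTS", "CAUSES",
  "COEXISTS_WITH", "COMPLICATES", "CONVERTS_TO", "DIAGNOSES", "DISRUPTS",
  "INHIBITS", "INTERACTS_WITH", "LOCATION_OF", "MEASURES", "METHOD_OF",
  "OCCURS_IN", "PART_OF", "PRECEDES", "PREDISPOSES", "PREVENTS", "PROCESS_OF",
  "PRODUCES", "STIMULATES", "TREATS", "USES"
)
COMPARATIVE_PREDICATES <- c("COMPARED_WITH", "HIGHER_THAN", "LOWER_THAN", "SAME_AS")
ALL_PREDICATES <- c(ASSOCIATIVE_PREDICATES, "ISA", COMPARATIVE_PREDICATES)

# Semantic types whose concepts are too generic to serve as a semantic head
# (used by empty-head marking).
NONINFORMATIVE_TYPES <- c(
  "Qualitative Concept", "Quantitative Concept", "Functional Concept",
  "Temporal Concept", "Idea or Concept", "Spatial Concept"
)

#' Strip a NEG_ prefix from a predicate label
#' @param predicate character vector of predicate labels.
#' @return the base predicate label(s).
#' @export
base_predicate <- function(predicate) sub("^NEG_", "", toupper(predicate))

#' Assemble a predication knowledge base
#'
#' A knowledge base bundles every resource the extraction pipeline consults:
#' the concept dictionary (with synonyms and semantic types), the semantic
#' group table, the concept hierarchy, the ontology of licensed
#' (subject type, PREDICATE, object type) triples, the indicator rules, the
#' gene alias index, the lexicon, the inference rules, and assorted word
#' lists (empty heads, negation triggers, coordination barriers, ...).
#'
#' @param concepts data.frame with columns `id`, `name`, `semtypes`
#'   (`;`-separated), `source` (`METATHESAURUS`, `GENE`, or `DOMAIN`).
#' @param synonyms data.frame with columns `surface`, `id`. Dysonymous
#'   synonyms are filtered out when the lookup index is built.
#' @param semgroups data.frame with columns `type`, `group`.
#' @param hierarchy data.frame with columns `child`, `parent` (concept ids).
#' @param ontology data.frame with columns `subject_type`, `predicate`,
#'   `object_type`, `source`.
#' @param rules data.frame of indicator rules as returned by
#'   [read_indicator_rules()].
#' @param gene_index data.frame with columns `alias`, `gene_id`, `symbol`.
#' @param lexicon data.frame as returned by [read_lexicon()].
#' @param inference_rules data.frame as returned by [read_inference_rules()].
#' @param word_lists named list of word lists (see [default_word_lists()]).
#' @param extensions named list of domain extensions (see
#'   [read_domain_extension()]).
#' @return an object of class `predication_kb`.
#' @export
predication_kb <- function(concepts, synonyms, semgroups, hierarchy, ontology,
                           rules, gene_index = NULL, lexicon = NULL,
                           inference_rules = NULL, word_lists = NULL,
                           extensions = list()) {
  wl <- default_word_lists()
  overrides <- word_lists %||% list()
  wl[names(overrides)] <- overrides
  word_lists <- wl
  if (is.null(gene_index)) {
    gene_index <- data.frame(alias = character(), gene_id = character(),
                             symbol = character(), stringsAsFactors = FALSE)
  }
  if (is.null(lexicon)) lexicon <- empty_lexicon()
  if (is.null(inference_rules)) {
    inference_rules <- data.frame(p1s = character(), p1p = character(), p1o = character(),
                                  p2s = character(), p2p = character(), p2o = character(),
                                  cs = character(), cp = character(), co = character(),
                                  stringsAsFactors = FALSE)
  }
  concepts$semtypes <- as.character(concepts$semtypes)
  kb <- structure(list(
    concepts = concepts,
    synonyms = synonyms,
    semgroups = semgroups,
    hierarchy = hierarchy,
    ontology = ontology,
    rules = rules,
    gene_index = gene_index,
    lexicon = lexicon,
    inference_rules = inference_rules,
    word_lists = word_lists,
    extensions = extensions
  ), class = "predication_kb")
  kb <- rebuild_kb_indexes(kb)
  validate_kb(kb)
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild derived lookup structures (synonym index minus dysonyms, gene index
# normalization, concept row lookup). Called by the constructor and after
# domain-extension application.
rebuild_kb_indexes <- function(kb) {
  kb$concept_by_id <- stats::setNames(seq_len(nrow(kb$concepts)), kb$concepts$id)
  syn <- kb$synonyms
  syn$surface <- normalize_surface(syn$surface)
  keep <- !vapply(seq_len(nrow(syn)), function(i) {
    cid <- syn$id[i]
    row <- kb$concept_by_id[[cid]]
    if (is.null(row) || is.na(row)) return(FALSE)
    is_dysonym(syn$surface[i], kb$concepts$name[row],
               exception_terms = kb$word_lists$dysonym_exceptions,
               explicit_list = kb$word_lists$dysonyms,
               concept_id = cid)
  }, logical(1))
  drop <- !vapply(syn$id, function(cid) {
    r <- kb$concept_by_id[[cid]]
    !is.null(r) && !is.na(r)
  }, logical(1))
  syn <- syn[keep & !drop, , drop = FALSE]
  syn <- unique(syn)
  kb$syn_index <- split(syn$id, syn$surface)
  kb$max_syn_tokens <- if (nrow(syn)) max(lengths(strsplit(syn$surface, " "))) else 1L
  gi <- kb$gene_index
  gi$alias <- normalize_surface(gi$alias)
  kb$gene_lookup <- split(seq_len(nrow(gi)), gi$alias)
  kb$gene_index_norm <- gi
  lex <- kb$lexicon
  lex$surface <- normalize_surface(lex$surface)
  kb$lex_index <- split(seq_len(nrow(lex)), lex$surface)
  kb$lexicon_norm <- lex
  kb$type_group <- stats::setNames(kb$semgroups$group, kb$semgroups$type)
  kb$parents <- split(kb$hierarchy$parent, kb$hierarchy$child)
  kb
}

normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  # hyphens written with surrounding spaces collapse to bare hyphens so that
  # token-reassembled spans match dictionary entries
  gsub(" ?- ?", "-", x)
}

#' Validate knowledge-base invariants
#'
#' Checks that the hierarchy is acyclic, that every semantic type used in the
#' ontology or concept dictionary has a semantic group, that predicate labels
#' are drawn from the configured inventory, and (as a warning) the licensing
#' closure: every predicate used by an indicator rule should appear in at
#' least one ontological predication.
#'
#' @param kb a `predication_kb`.
#' @return invisibly, a character vector of warnings (empty when clean).
#' @export
validate_kb <- function(kb) {
  warnings <- character()
  bad_pred <- setdiff(base_predicate(kb$ontology$predicate), ALL_PREDICATES)
  dom_preds <- unlist(lapply(kb$extensions, function(e) {
    c(base_predicate(e$ontology$predicate %||% character()),
      base_predicate(e$rules$predicate %||% character()))
  }))
  bad_pred <- setdiff(bad_pred, dom_preds)
  if (length(bad_pred)) {
    stop("unknown predicate label(s) in ontology: ", paste(bad_pred, collapse = ", "))
  }
  if (hierarchy_has_cycle(kb$hierarchy)) stop("concept hierarchy contains a cycle")
  rule_preds <- setdiff(base_predicate(kb$rules$predicate), dom_preds)
  missing <- setdiff(rule_preds, base_predicate(kb$ontology$predicate))
  if (length(missing)) {
    warnings <- c(warnings, paste0(
      "indicator rules use predicate(s) with no ontological predication: ",
      paste(sort(missing), collapse = ", ")))
  }
  no_type <- kb$concepts$semtypes == "" | is.na(kb$concepts$semtypes)
  if (any(no_type)) stop("concept(s) without a semantic type: ",
                         paste(kb$concepts$id[no_type], collapse = ", "))
  if (anyDuplicated(kb$concepts$id)) {
    stop("duplicate concept id(s): ",
         paste(unique(kb$concepts$id[duplicated(kb$concepts$id)]), collapse = ", "))
  }
  for (w in warnings) warning(w, call. = FALSE)
  invisible(warnings)
}

hierarchy_has_cycle <- function(hierarchy) {
  if (!nrow(hierarchy)) return(FALSE)
  nodes <- unique(c(hierarchy$child, hierarchy$parent))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  parents <- split(hierarchy$parent, hierarchy$child)
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (p in parents[[n]] %||% character()) if (visit(p)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

#' @export
print.predication_kb <- function(x, ...) {
  cat("<predication_kb>\n")
  cat("  concepts:        ", nrow(x$concepts), "\n")
  cat("  synonyms:        ", nrow(x$synonyms), "\n")
  cat("  ontology triples:", nrow(x$ontology), "\n")
  cat("  indicator rules: ", nrow(x$rules), "\n")
  cat("  hierarchy edges: ", nrow(x$hierarchy), "\n")
  cat("  gene aliases:    ", nrow(x$gene_index), "\n")
  if (length(x$extensions))
    cat("  extensions:      ", paste(names(x$extensions), collapse = ", "), "\n")
  invisible(x)
}

#' Semantic types of a concept
#' @param kb a `predication_kb`.
#' @param id concept id.
#' @return character vector of semantic type names.
#' @export
concept_types <- function(kb, id) {
  row <- kb$concept_by_id[[id]]
  if (is.null(row) || is.na(row)) return(character())
  strsplit(kb$concepts$semtypes[row], ";", fixed = TRUE)[[1]]
}

#' Semantic group of a semantic type
#' @param kb a `predication_kb`.
#' @param type semantic type name(s).
#' @return character vector of group names (NA when unknown).
#' @export
semantic_group <- function(kb, type) {
  unname(kb$type_group[type])
}

#' Ancestor test in the concept hierarchy
#'
#' `is_ancestor(kb, a, b)` is `TRUE` when `a` is a strict ancestor of `b`
#' under the transitive closure of the hierarchy edges; a concept is never
#' its own ancestor.
#'
#' @param kb a `predication_kb`.
#' @param ancestor,descendant concept ids.
#' @return logical scalar.
#' @export
is_ancestor <- function(kb, ancestor, descendant) {
  if (identical(ancestor, descendant)) return(FALSE)
  seen <- character()
  frontier <- descendant
  while (length(frontier)) {
    nxt <- unique(unlist(kb$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (ancestor %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Query licensed orientations for a candidate predication
#'
#' An extracted predication must be licensed by an ontological predication.
#' `FORWARD` is licensed when some (subject type, predicate, object type)
#' combination is in the ontology; `INVERSE` when the transposed triple is,
#' and the querying indicator rule allows inverse orientation (locative and
#' stative predicates such as LOCATION_OF and PART_OF, whose semantic roles
#' can oppose surface order).
#'
#' @param subject_types,object_types character vectors of semantic types.
#' @param predicate predicate label (a NEG_ prefix is ignored for licensing).
#' @param ontology ontology data.frame (`subject_type`, `predicate`,
#'   `object_type`) or a `predication_kb`.
#' @param allow_inverse may the INVERSE orientation be reported?
#' @return character vector, a subset of `c("FORWARD", "INVERSE")`.
#' @export
licensed_orientations <- function(subject_types, predicate, object_types,
                                  ontology, allow_inverse = FALSE) {
  if (inherits(ontology, "predication_kb")) ontology <- ontology$ontology
  stopifnot(length(subject_types) > 0, length(object_types) > 0)
  pred <- base_predicate(predicate)
  rel <- ontology[ontology$predicate == pred, , drop = FALSE]
  out <- character()
  if (any(rel$subject_type %in% subject_types & rel$object_type %in% object_types))
    out <- c(out, "FORWARD")
  if (allow_inverse &&
      any(rel$subject_type %in% object_types & rel$object_type %in% subject_types))
    out <- c(out, "INVERSE")
  out
}

#' Dysonym test for a concept synonym
#'
#' A dysonym is a spurious synonym valid only in a narrow source context and
#' suppressed during concept mapping. A synonym is a dysonym when it is a
#' proper word-level substring of the concept's preferred name and the
#' residual words (punctuation stripped) are not all general exception terms
#' (such as "procedure", "disorder", "gene"), or when the (synonym, concept)
#' pair is on the explicit dysonym list.
#'
#' @param synonym surface string registered for the concept.
#' @param preferred_name the concept's preferred name.
#' @param exception_terms character vector of residual terms that do not
#'   invalidate the mapping.
#' @param explicit_list data.frame with columns `surface`, `id` of dysonyms
#'   that do not satisfy the substring constraint.
#' @param concept_id id of the concept (used with `explicit_list`).
#' @return logical scalar.
#' @export
is_dysonym <- function(synonym, preferred_name,
                       exception_terms = character(),
                       explicit_list = NULL, concept_id = NULL) {
  syn <- normalize_surface(synonym)
  if (!is.null(explicit_list) && nrow(explicit_list) &&
      any(normalize_surface(explicit_list$surface) == syn &
          explicit_list$id == (concept_id %||% ""))) {
    return(TRUE)
  }
  name_words <- surface_words(preferred_name)
  syn_words <- surface_words(syn)
  if (identical(syn_words, name_words)) return(FALSE)
  pos <- word_subsequence_at(syn_words, name_words)
  if (is.na(pos)) return(FALSE)
  residual <- name_words[-(pos:(pos + length(syn_words) - 1L))]
  !all(residual %in% tolower(exception_terms))
}

surface_words <- function(x) {
  w <- strsplit(gsub("[[:punct:]]+", " ", tolower(x)), "\\s+")[[1]]
  w[nzchar(w)]
}

word_subsequence_at <- function(needle, haystack) {
  n <- length(needle); h <- length(haystack)
  if (n == 0 || n > h) return(NA_integer_)
  for (i in seq_len(h - n + 1L)) {
    if (all(haystack[i:(i + n - 1L)] == needle)) return(i)
  }
  NA_integer_
}

#' Default word lists
#'
#' The configured word lists seeding the pipeline: empty heads, relational
#' nouns, negation triggers and pseudo-negation patterns, coordination
#' barriers, relativizers, sortal-anaphor determiners, comparative scale
#' cues, dysonym machinery, and the class of nominal indicators that reject
#' prepositionally cued subjects. Lists are lower-cased and duplicate-free;
#' each is an open configuration seeded with its documented members.
#'
#' @return a named list.
#' @export
default_word_lists <- function() {
  list(
    empty_heads = c("variant", "variants", "polymorphism", "polymorphisms",
                    "concentration", "synthesis", "metabolism"),
    relational_nouns = c("application", "analysis", "synthesis"),
    negation_triggers = data.frame(
      trigger = c("not", "neither", "no", "without", "unable", "failure",
                  "fail to", "fails to", "failed to", "no evidence", "absent"),
      direction = c(rep("pre", 10), "post"),
      stringsAsFactors = FALSE),
    pseudo_negation = c("not only", "not necessarily", "without doubt",
                        "no more than", "not as"),
    coordination_barriers = c("between", "either", "against", "such as",
                              "including"),
    relativizers = c("which", "who", "whom", "whose", "that"),
    anaphor_determiners = c("this", "these", "such", "each", "those", "the"),
    comparative_scales = data.frame(
      cue = c("effective", "safe", "potent", "efficacious"),
      scale = c("EFFECTIVENESS", "SAFETY", "POTENCY", "EFFECTIVENESS"),
      stringsAsFactors = FALSE),
    dysonyms = data.frame(surface = character(), id = character(),
                          stringsAsFactors = FALSE),
    dysonym_exceptions = c("procedure", "disorder", "gene"),
    nonprep_subject_nouns = c("cause", "causes"),
    noninformative_types = NONINFORMATIVE_TYPES
  )
}
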