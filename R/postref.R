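# Post-referential analysis: empty-head marking, NP coordination detection,
# and optional sortal anaphora resolution over the concept-annotated phrase
# sequence.

#' Mark empty heads
#'
#' When an NP head is on the empty-head list (generic nouns such as
#' "variants", "concentration") and its best mapping is absent or maps only
#' to a non-informative semantic type (Qualitative Concept and kin), the
#' first modifier to the left of the head is relabeled as the semantic head.
#' Never fires on an NP without modifiers.
#'
#' @param phrase a phrase.
#' @param tokens sentence tokens.
#' @param word_lists knowledge-base word lists (`empty_heads`,
#'   `noninformative_types`).
#' @return the phrase with `sem_head` possibly moved.
#' @export
mark_empty_heads <- function(phrase, tokens, word_lists) {
  if (!phrase$kind %in% c("NP", "PP") || is.na(phrase$head)) return(phrase)
  left_mods <- phrase$mods[phrase$mods < phrase$head]
  if (!length(left_mods)) return(phrase)
  head_word <- tolower(tokens$text[phrase$head])
  if (!head_word %in% word_lists$empty_heads &&
      !tokens$lemma[phrase$head] %in% word_lists$empty_heads) {
    return(phrase)
  }
  head_maps <- Filter(function(m) m$start_tok <= phrase$head &
                        m$end_tok >= phrase$head, phrase$mappings)
  informative <- any(vapply(head_maps, function(m) {
    !all(m$semtypes %in% word_lists$noninformative_types)
  }, logical(1)))
  if (informative) return(phrase)
  phrase$sem_head <- max(left_mods)
  phrase
}

#' Compatibility of two NPs for coordination
#'
#' Two NPs are compatible when the semantic types of their semantic heads
#' belong to the same semantic group, or they have the same head word, or
#' both heads are relational nouns.
#'
#' @param np1,np2 phrases with mappings.
#' @param tokens1,tokens2 token tables of the phrases' sentences (the same
#'   table when both phrases come from one sentence).
#' @param kb a `predication_kb`.
#' @return logical scalar.
#' @export
np_compatible <- function(np1, np2, tokens1, tokens2 = tokens1, kb) {
  h1 <- if (!is.na(np1$head)) tokens1$lemma[np1$head] else NA_character_
  h2 <- if (!is.na(np2$head)) tokens2$lemma[np2$head] else NA_character_
  if (!is.na(h1) && !is.na(h2) && identical(h1, h2)) return(TRUE)
  rel <- kb$word_lists$relational_nouns
  if (!is.na(h1) && !is.na(h2) && h1 %in% rel && h2 %in% rel) return(TRUE)
  m1 <- phrase_best_mapping(np1); m2 <- phrase_best_mapping(np2)
  if (is.null(m1) || is.null(m2)) return(FALSE)
  g1 <- stats::na.omit(semantic_group(kb, m1$semtypes))
  g2 <- stats::na.omit(semantic_group(kb, m2$semtypes))
  length(intersect(g1, g2)) > 0
}

#' Detect NP coordination
#'
#' For each coordinating conjunction (including multi-word expressions such
#' as "followed by" and "but not") whose neighbouring phrases are compatible
#' NPs, a coordination structure is built and extended leftward across
#' comma-separated compatible NPs, terminating at an incompatible NP or a
#' barrier word (between, either, against, such as, including).
#' Pre-conjunction words ("either", "both") are determiners and are ignored.
#'
#' @param phrases phrase list with mappings.
#' @param tokens sentence tokens.
#' @param kb a `predication_kb`.
#' @return list of coordination structures, each a list with `conj` (phrase
#'   index) and `conjuncts` (ordered phrase indices).
#' @export
detect_coordination <- function(phrases, tokens, kb) {
  out <- list()
  barriers <- kb$word_lists$coordination_barriers
  for (ci in seq_along(phrases)) {
    if (phrases[[ci]]$kind != "CONJ") next
    left <- prev_matching(phrases, ci, function(p) p$kind %in% c("NP", "PP"))
    right <- next_matching(phrases, ci, function(p) p$kind %in% c("NP", "PP"))
    if (is.na(left) || is.na(right)) next
    if (!is.na(left) && left != ci - 1L &&
        !all_punct_between(phrases, left, ci)) next
    if (right != ci + 1L && !all_punct_between(phrases, ci, right)) next
    if (!np_compatible(phrases[[left]], phrases[[right]], tokens, tokens, kb)) next
    conjuncts <- c(left, right)
    # series coordination: extend leftward over ", NP" pairs
    k <- left
    repeat {
      comma <- k - 1L
      if (comma < 1L || phrases[[comma]]$kind != "PUNCT" ||
          tokens$text[phrases[[comma]]$first] != ",") break
      cand <- comma - 1L
      if (cand < 1L || !phrases[[cand]]$kind %in% c("NP", "PP")) break
      if (phrase_has_barrier(phrases[[cand]], tokens, barriers)) break
      if (!np_compatible(phrases[[cand]], phrases[[k]], tokens, tokens, kb)) break
      conjuncts <- c(cand, conjuncts)
      k <- cand
    }
    out[[length(out) + 1L]] <- list(conj = ci, conjuncts = conjuncts)
  }
  out
}

prev_matching <- function(phrases, i, pred) {
  j <- i - 1L
  while (j >= 1L) {
    if (pred(phrases[[j]])) return(j)
    if (phrases[[j]]$kind != "PUNCT") return(NA_integer_)
    j <- j - 1L
  }
  NA_integer_
}

next_matching <- function(phrases, i, pred) {
  j <- i + 1L
  while (j <= length(phrases)) {
    if (pred(phrases[[j]])) return(j)
    if (phrases[[j]]$kind != "PUNCT") return(NA_integer_)
    j <- j + 1L
  }
  NA_integer_
}

all_punct_between <- function(phrases, a, b) {
  if (b - a <= 1L) return(TRUE)
  all(vapply(phrases[(a + 1L):(b - 1L)], function(p) p$kind == "PUNCT", logical(1)))
}

phrase_has_barrier <- function(phrase, tokens, barriers) {
  txt <- tolower(tokens$text[phrase$first:phrase$last])
  any(txt %in% barriers)
}

# which coordination structure (index) contains phrase p as a conjunct?
coordination_of <- function(coords, p) {
  for (k in seq_along(coords)) if (p %in% coords[[k]]$conjuncts) return(k)
  NA_integer_
}

np_is_plural <- function(phrase, tokens) {
  if (is.na(phrase$head)) return(FALSE)
  has_feature(tokens$features[phrase$head], "number", "plural")
}

#' Resolve sortal anaphora
#'
#' Candidate anaphors are NPs containing an anaphor-indicating determiner or
#' adjective ("this", "these", "such", "each", ...) and carrying a concept
#' mapping. Candidates in an appositive construction (NP, NP where the
#' second NP's concept is a hierarchy descendant of the first's) are
#' filtered out. Antecedents are searched right to left over the preceding
#' discourse; a valid antecedent's concept must be a hierarchy descendant of
#' the anaphor's concept (the anaphor is the more general term) and agree in
#' grammatical number. A plural anaphor whose nearest antecedent is a
#' conjunct resolves to all conjuncts of that coordination
#' (set-membership anaphora).
#'
#' @param doc_sentences list of annotated sentences (each with `tokens`,
#'   `phrases`, `coordinations`).
#' @param kb a `predication_kb`.
#' @return list of links, each with `anaphor` = c(sentence, phrase),
#'   `antecedents` = list of c(sentence, phrase), `kind`
#'   (`SIMPLE`/`SET_MEMBERSHIP`).
#' @export
resolve_sortal_anaphora <- function(doc_sentences, kb) {
  links <- list()
  dets <- kb$word_lists$anaphor_determiners
  for (s in seq_along(doc_sentences)) {
    sent <- doc_sentences[[s]]
    for (p in seq_along(sent$phrases)) {
      ph <- sent$phrases[[p]]
      if (!ph$kind %in% c("NP", "PP") || is.na(ph$head)) next
      words <- tolower(sent$tokens$text[ph$first:ph$last])
      if (!any(words %in% dets)) next
      am <- phrase_best_mapping(ph)
      if (is.null(am)) next
      if (is_appositive_anaphor(sent, p, kb)) next
      link <- find_antecedents(doc_sentences, s, p, am, kb)
      if (!is.null(link)) links[[length(links) + 1L]] <- link
    }
  }
  links
}

is_appositive_anaphor <- function(sent, p, kb) {
  phrases <- sent$phrases
  if (p + 2L > length(phrases)) return(FALSE)
  comma <- phrases[[p + 1L]]
  nxt <- phrases[[p + 2L]]
  if (comma$kind != "PUNCT" ||
      sent$tokens$text[comma$first] != "," ||
      !nxt$kind %in% c("NP", "PP")) return(FALSE)
  am <- phrase_best_mapping(phrases[[p]])
  bm <- phrase_best_mapping(nxt)
  if (is.null(am) || is.null(bm)) return(FALSE)
  is_ancestor(kb, am$concept_id, bm$concept_id)
}

find_antecedents <- function(doc_sentences, s, p, am, kb) {
  anaphor_plural <- np_is_plural(doc_sentences[[s]]$phrases[[p]],
                                 doc_sentences[[s]]$tokens)
  for (ss in rev(seq_len(s))) {
    sent <- doc_sentences[[ss]]
    upto <- if (ss == s) p - 1L else length(sent$phrases)
    if (upto < 1L) next
    for (pp in rev(seq_len(upto))) {
      cand <- sent$phrases[[pp]]
      if (!cand$kind %in% c("NP", "PP")) next
      cm <- phrase_best_mapping(cand)
      if (is.null(cm)) next
      if (!is_ancestor(kb, am$concept_id, cm$concept_id)) next
      ck <- coordination_of(sent$coordinations, pp)
      if (!is.na(ck) && anaphor_plural) {
        conjuncts <- sent$coordinations[[ck]]$conjuncts
        ok <- vapply(conjuncts, function(q) {
          qm <- phrase_best_mapping(sent$phrases[[q]])
          !is.null(qm) && is_ancestor(kb, am$concept_id, qm$concept_id)
        }, logical(1))
        if (all(ok)) {
          return(list(anaphor = c(s, p),
                      antecedents = lapply(conjuncts, function(q) c(ss, q)),
                      kind = "SET_MEMBERSHIP"))
        }
      }
      if (anaphor_plural != np_is_plural(cand, sent$tokens)) next
      return(list(anaphor = c(s, p), antecedents = list(c(ss, pp)),
                  kind = "SIMPLE"))
    }
  }
  NULL
}
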