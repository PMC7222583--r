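# Relational analysis, part 1: hypernymic predications, comparative
# predications, and trigger detection with indicator rules.

new_predication <- function(subj, predicate, obj, sentence,
                            subj_phrase = NA_integer_, obj_phrase = NA_integer_,
                            negated = FALSE, inferred = FALSE,
                            indicator_type = NA_character_,
                            indicator_text = NA_character_,
                            indicator_tok = NA_integer_, rule = NULL,
                            scale = NA_character_, sentence2 = NA_integer_) {
  list(subj = subj, predicate = predicate, obj = obj, negated = negated,
       inferred = inferred, indicator_type = indicator_type,
       indicator_text = indicator_text, indicator_tok = indicator_tok,
       rule = rule, scale = scale, sentence = sentence, sentence2 = sentence2,
       subj_phrase = subj_phrase, obj_phrase = obj_phrase)
}

predication_key <- function(p) {
  paste(p$subj$concept_id, if (p$negated) paste0("NEG_", p$predicate) else p$predicate,
        p$obj$concept_id, p$inferred, sep = "|")
}

HYPERNYM_EXCLUDED_GROUPS <- c("Anatomy", "Concepts & Ideas")

#' Extract hypernymic (ISA) predications
#'
#' Candidate hyponym/hypernym pairs come from three syntactic
#' manifestations: (a) the modifier and head of one NP ("the anticonvulsant
#' gabapentin"), (b) appositive structures, including "such as"
#' constructions and comma appositives, and (c) two NPs linked by a form of
#' *be* or *remain* within a window of 5 phrases. A pair is emitted as
#' hyponym-ISA-hypernym when both concepts share a semantic group (excluding
#' the Anatomy and Concepts & Ideas groups) and stand in a hierarchical
#' relationship.
#'
#' @param sent an annotated sentence (with `tokens`, `phrases`,
#'   `coordinations`).
#' @param kb a `predication_kb`.
#' @return list of ISA predications.
#' @export
resolve_hypernymy <- function(sent, kb) {
  out <- list()
  phrases <- sent$phrases
  add_pair <- function(m1, m2, p1, p2, itype, itext, itok) {
    pair <- orient_isa(m1, m2, kb)
    if (is.null(pair)) return()
    out[[length(out) + 1L]] <<- new_predication(
      subj = pair$hypo, obj = pair$hyper, predicate = "ISA",
      sentence = sent$index, subj_phrase = p1, obj_phrase = p2,
      indicator_type = itype, indicator_text = itext, indicator_tok = itok)
  }
  # (a) modifier-head inside one NP
  for (p in seq_along(phrases)) {
    ph <- phrases[[p]]
    if (!ph$kind %in% c("NP", "PP") || is.na(ph$head)) next
    hm <- Filter(function(m) m$start_tok <= ph$head & m$end_tok >= ph$head,
                 ph$mappings)
    hm <- if (length(hm)) hm[[1]] else next
    mods <- Filter(function(m) m$end_tok < hm$start_tok, ph$mappings)
    for (mm in rev(mods)) {
      n0 <- length(out)
      add_pair(mm, hm, p, p, "hypernym", "modifier-head", ph$head)
      if (length(out) > n0) break
    }
  }
  # (b) appositives: NP [such as] NP ; NP , NP ; NP ( NP )
  for (p in seq_along(phrases)) {
    ph <- phrases[[p]]
    if (!ph$kind %in% c("NP", "PP")) next
    m1 <- phrase_best_mapping(ph)
    if (is.null(m1)) next
    if (p + 1L <= length(phrases) && phrases[[p + 1L]]$kind == "APPOS" &&
        p + 2L <= length(phrases) && phrases[[p + 2L]]$kind %in% c("NP", "PP")) {
      m2 <- phrase_best_mapping(phrases[[p + 2L]])
      if (!is.null(m2)) add_pair(m2, m1, p + 2L, p, "hypernym", "such as",
                                 phrases[[p + 1L]]$first)
    }
    if (p + 2L <= length(phrases) && phrases[[p + 1L]]$kind == "PUNCT" &&
        sent$tokens$text[phrases[[p + 1L]]$first] %in% c(",", "(") &&
        phrases[[p + 2L]]$kind %in% c("NP", "PP") &&
        is.na(coordination_of(sent$coordinations, p)) &&
        is.na(coordination_of(sent$coordinations, p + 2L))) {
      m2 <- phrase_best_mapping(phrases[[p + 2L]])
      if (!is.null(m2)) add_pair(m2, m1, p + 2L, p, "hypernym", "appositive",
                                 phrases[[p + 1L]]$first)
    }
  }
  # (c) BE/remain within a 5-phrase window
  for (p in seq_along(phrases)) {
    ph <- phrases[[p]]
    if (ph$kind != "VERB") next
    tok <- ph$first
    if (!(has_feature(sent$tokens$features[tok], "be", "1") ||
          sent$tokens$lemma[tok] == "remain") ||
        sent$tokens$pos[tok] != "verb") next
    left <- right <- NULL
    for (q in rev(seq_len(p - 1L))) {
      if (p - q > 5L) break
      if (phrases[[q]]$kind %in% c("NP", "PP")) {
        left <- phrase_best_mapping(phrases[[q]])
        if (!is.null(left)) { lp <- q; break }
      }
    }
    for (q in seq(p + 1L, length.out = max(0L, length(phrases) - p))) {
      if (q - p > 5L) break
      if (phrases[[q]]$kind %in% c("NP", "PP")) {
        right <- phrase_best_mapping(phrases[[q]])
        if (!is.null(right)) { rp <- q; break }
      }
    }
    if (!is.null(left) && !is.null(right)) {
      add_pair(left, right, lp, rp, "hypernym", sent$tokens$text[tok], tok)
    }
  }
  out
}

# order an (m1 candidate-hyponym, m2 candidate-hypernym) pair by the
# hierarchy; returns NULL when the semantic constraints fail
orient_isa <- function(m1, m2, kb) {
  g1 <- unique(stats::na.omit(semantic_group(kb, m1$semtypes)))
  g2 <- unique(stats::na.omit(semantic_group(kb, m2$semtypes)))
  shared <- intersect(g1, g2)
  shared <- setdiff(shared, HYPERNYM_EXCLUDED_GROUPS)
  if (!length(shared)) return(NULL)
  if (is_ancestor(kb, m2$concept_id, m1$concept_id)) {
    list(hypo = m1, hyper = m2)
  } else if (is_ancestor(kb, m1$concept_id, m2$concept_id)) {
    list(hypo = m2, hyper = m1)
  } else NULL
}

#' Extract comparative predications
#'
#' Two families of lexico-syntactic patterns are interpreted. A stated
#' comparison (`compare/comparison (of) Term1 with/to Term2`) yields
#' COMPARED_WITH. A scaled comparison (`Term1 BE [not] as ADJ as Term2`,
#' `Term1 BE more/less ADJ than Term2`) yields COMPARED_WITH plus a
#' relative-ranking predication (SAME_AS, HIGHER_THAN, or LOWER_THAN; a
#' negated equality reads as LOWER_THAN) whose scale is named by the
#' adjective cue (e.g. EFFECTIVENESS for "effective"). Compared terms must
#' share a semantic group.
#'
#' @inheritParams resolve_hypernymy
#' @param ctx extraction context (used to mark compared terms as consumed
#'   arguments); may be NULL.
#' @return list of predications.
#' @export
process_comparatives <- function(sent, kb, ctx = NULL) {
  out <- list()
  tokens <- sent$tokens
  phrases <- sent$phrases
  scales <- kb$word_lists$comparative_scales
  emit <- function(subj, obj, sp, op, pred, scale, itok) {
    out[[length(out) + 1L]] <<- new_predication(
      subj = subj, obj = obj, predicate = pred, sentence = sent$index,
      subj_phrase = sp, obj_phrase = op, indicator_type = "comparative",
      indicator_text = tokens$text[itok], indicator_tok = itok,
      scale = scale)
    if (!is.null(ctx)) { mark_used(ctx, sp, -1L); mark_used(ctx, op, -1L) }
  }
  same_group <- function(m1, m2) {
    length(intersect(stats::na.omit(semantic_group(kb, m1$semtypes)),
                     stats::na.omit(semantic_group(kb, m2$semtypes)))) > 0
  }
  # pattern 1: compare/comparison (of) T1 with/to T2
  for (i in seq_len(nrow(tokens))) {
    if (!tokens$lemma[i] %in% c("compare", "comparison")) next
    p1 <- phrase_at_or_after(phrases, i, c("NP", "PP"))
    if (is.na(p1)) next
    if (tokens$lemma[i] == "comparison" && !is.na(phrases[[p1]]$prep) &&
        tokens$lemma[phrases[[p1]]$prep] != "of") next
    m1 <- phrase_best_mapping(phrases[[p1]])
    if (is.null(m1)) next
    p2 <- NA_integer_
    for (q in seq(p1 + 1L, length.out = max(0L, length(phrases) - p1))) {
      if (phrases[[q]]$kind == "PP" &&
          tokens$lemma[phrases[[q]]$prep] %in% c("with", "to")) { p2 <- q; break }
      if (!phrases[[q]]$kind %in% c("PUNCT", "OTHER", "ADJ")) break
    }
    if (is.na(p2)) next
    m2 <- phrase_best_mapping(phrases[[p2]])
    if (is.null(m2) || !same_group(m1, m2)) next
    emit(m1, m2, p1, p2, "COMPARED_WITH", NA_character_, i)
  }
  # pattern 2: T1 BE [not] (as ADJ as | more/less ADJ than) T2
  for (i in seq_len(nrow(tokens))) {
    hit <- match_scaled_comparison(tokens, i)
    if (is.null(hit)) next
    be <- find_be_before(tokens, i)
    t1p <- NA_integer_
    if (!is.na(be)) {
      bph <- which(vapply(phrases, function(p) p$first <= be && p$last >= be, logical(1)))[1]
      for (q in rev(seq_len(bph - 1L))) {
        if (phrases[[q]]$kind %in% c("NP", "PP") &&
            !is.null(phrase_best_mapping(phrases[[q]]))) { t1p <- q; break }
      }
    }
    if (is.na(t1p)) next
    t2p <- NA_integer_
    for (q in seq_along(phrases)) {
      if (phrases[[q]]$last > hit$end && phrases[[q]]$kind %in% c("NP", "PP") &&
          !is.null(phrase_best_mapping(phrases[[q]]))) { t2p <- q; break }
    }
    if (is.na(t2p)) next
    m1 <- phrase_best_mapping(phrases[[t1p]])
    m2 <- phrase_best_mapping(phrases[[t2p]])
    if (!same_group(m1, m2)) next
    negated <- !is.na(be) && any(tokens$lemma[seq(be, i)] == "not")
    rank <- if (hit$kind == "equative") {
      if (negated) "LOWER_THAN" else "SAME_AS"
    } else if (hit$kind == "more") {
      if (negated) "LOWER_THAN" else "HIGHER_THAN"
    } else {
      if (negated) "HIGHER_THAN" else "LOWER_THAN"
    }
    scale <- scales$scale[match(tokens$lemma[hit$adj], scales$cue)]
    emit(m1, m2, t1p, t2p, "COMPARED_WITH", NA_character_, hit$adj)
    emit(m1, m2, t1p, t2p, rank, scale, hit$adj)
  }
  out
}

match_scaled_comparison <- function(tokens, i) {
  lower <- tolower(tokens$text)
  n <- nrow(tokens)
  if (lower[i] == "as" && i + 2L <= n && tokens$pos[i + 1L] == "adj" &&
      lower[i + 2L] == "as") {
    return(list(kind = "equative", adj = i + 1L, end = i + 2L))
  }
  if (lower[i] %in% c("more", "less") && i + 2L <= n &&
      tokens$pos[i + 1L] == "adj" && lower[i + 2L] == "than") {
    return(list(kind = if (lower[i] == "more") "more" else "less",
                adj = i + 1L, end = i + 2L))
  }
  NULL
}

find_be_before <- function(tokens, i) {
  for (j in rev(seq_len(i - 1L))) {
    if (has_feature(tokens$features[j], "be", "1")) return(j)
    if (!(tokens$pos[j] %in% c("adv", "aux", "modal") ||
          tolower(tokens$text[j]) %in% c("not"))) return(NA_integer_)
  }
  NA_integer_
}

phrase_at_or_after <- function(phrases, tok, kinds) {
  for (q in seq_along(phrases)) {
    if (phrases[[q]]$last >= tok && phrases[[q]]$kind %in% kinds &&
        phrases[[q]]$first > tok) {
      return(q)
    }
  }
  NA_integer_
}

#' Detect indicator-rule trigger instances
#'
#' Single-word rules match on lemma (or surface) plus part-of-speech; noun
#' rules fire on NP/PP heads, preposition rules on a PP's preposition
#' (unless the preceding head word subcategorizes for it), adjective rules
#' on adjective tokens. Multi-word and brace rules (`{increase,odds}`) match
#' token sequences, braces allowing intervening determiners and modifiers.
#' Structural MOD_HEAD rules fire on NPs whose modifier and head mappings
#' are licensed for the rule's predicate. Verbal instances are flagged
#' passive when a past participle follows a BE form or is followed by a
#' by-phrase.
#'
#' @inheritParams resolve_hypernymy
#' @return list of indicator instances (rule, token span, phrase, class,
#'   passive flag), ordered by position.
#' @export
detect_triggers <- function(sent, kb) {
  tokens <- sent$tokens
  phrases <- sent$phrases
  rules <- kb$rules
  out <- list()
  add <- function(rule_row, tok, tok_end, phrase, class, passive = FALSE) {
    out[[length(out) + 1L]] <<- list(
      rule = as.list(rules[rule_row, ]), tok = tok, tok_end = tok_end,
      phrase = phrase, class = class, passive = passive)
  }
  phrase_of_token <- function(t) {
    for (q in seq_along(phrases)) {
      if (phrases[[q]]$first <= t && phrases[[q]]$last >= t) return(q)
    }
    NA_integer_
  }
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    if (rule$pos == "MOD_HEAD") {
      for (q in seq_along(phrases)) {
        ph <- phrases[[q]]
        if (!ph$kind %in% c("NP", "PP") || is.na(ph$head)) next
        hm <- Filter(function(m) m$start_tok <= ph$head & m$end_tok >= ph$head,
                     ph$mappings)
        if (!length(hm)) next
        mods <- Filter(function(m) m$end_tok < hm[[1]]$start_tok, ph$mappings)
        if (!length(mods)) next
        lic <- any(vapply(mods, function(mm) {
          length(licensed_orientations(mm$semtypes, rule$predicate,
                                       hm[[1]]$semtypes, kb)) > 0
        }, logical(1)))
        if (lic) add(r, ph$head, ph$head, q, "mod_head")
      }
      next
    }
    if (grepl("[{ ]", rule$lexeme)) {
      hits <- match_phrase_lexeme(tokens, rule$lexeme)
      for (h in hits) {
        add(r, h[1], h[2], phrase_of_token(h[1]),
            if (rule$pos == "verb") "verb" else "noun",
            passive = FALSE)
      }
      next
    }
    for (t in seq_len(nrow(tokens))) {
      if (!(tokens$lemma[t] == rule$lexeme ||
            tolower(tokens$text[t]) == rule$lexeme)) next
      q <- phrase_of_token(t)
      if (is.na(q)) next
      if (rule$pos == "verb" && tokens$pos[t] == "verb") {
        add(r, t, t, q, "verb", passive = is_passive(sent, t))
      } else if (rule$pos == "noun" && tokens$pos[t] %in% c("noun") &&
                 !is.na(phrases[[q]]$head) && phrases[[q]]$head == t) {
        add(r, t, t, q, "noun")
      } else if (rule$pos == "prep" && tokens$pos[t] == "prep" &&
                 phrases[[q]]$kind %in% c("PP") &&
                 !is.na(phrases[[q]]$prep) && phrases[[q]]$prep == t) {
        if (!prep_subcategorized(sent, q, tokens$lemma[t], kb)) add(r, t, t, q, "prep")
      } else if (rule$pos == "adj" && tokens$pos[t] == "adj") {
        add(r, t, t, q, "adj")
      }
    }
  }
  ord <- order(vapply(out, `[[`, 0L, "tok"),
               vapply(out, function(x) x$rule$predicate, ""))
  out[ord]
}

# brace lexeme "{increase,odds}": words in order, determiners/modifiers
# allowed between; plain multi-word lexeme: contiguous
match_phrase_lexeme <- function(tokens, lexeme) {
  gapped <- grepl("^\\{", lexeme)
  words <- strsplit(gsub("[{}]", "", lexeme), "[ ,]+")[[1]]
  lower <- tolower(tokens$text)
  hits <- list()
  n <- nrow(tokens)
  for (i in seq_len(n)) {
    if (!(lower[i] == words[1] || tokens$lemma[i] == words[1])) next
    pos <- i; ok <- TRUE
    for (w in words[-1]) {
      j <- pos + 1L
      if (gapped) {
        while (j <= n && (tokens$pos[j] %in% c("det", "adj", "num", "adv") ||
                          lower[j] == words[1])) j <- j + 1L
      }
      if (j > n || !(lower[j] == w || tokens$lemma[j] == w)) { ok <- FALSE; break }
      pos <- j
    }
    if (ok) hits[[length(hits) + 1L]] <- c(i, pos)
  }
  hits
}

is_passive <- function(sent, t) {
  tokens <- sent$tokens
  if (!has_feature(tokens$features[t], "tense", "pastpart")) return(FALSE)
  j <- t - 1L
  while (j >= 1L && tokens$pos[j] %in% c("adv")) j <- j - 1L
  if (j >= 1L && (has_feature(tokens$features[j], "be", "1"))) return(TRUE)
  j <- t + 1L
  while (j <= nrow(tokens) && tokens$pos[j] %in% c("adv")) j <- j + 1L
  j <= nrow(tokens) && tokens$lemma[j] == "by" && tokens$pos[j] == "prep"
}

# is `prep` subcategorized for by the head word preceding the PP?
prep_subcategorized <- function(sent, pp_idx, prep, kb) {
  phrases <- sent$phrases
  if (pp_idx <= 1L) return(FALSE)
  before <- phrases[[pp_idx - 1L]]
  ht <- if (before$kind %in% c("NP", "PP") && !is.na(before$head)) {
    before$head
  } else if (before$kind == "VERB") before$first else NA_integer_
  if (is.na(ht)) return(FALSE)
  lemma <- sent$tokens$lemma[ht]
  lex <- kb$lexicon_norm
  feats <- lex$features[lex$base == lemma]
  subcats <- unlist(lapply(feats, function(f) {
    v <- lex_feature(f, "subcat")
    if (is.na(v)) character() else strsplit(v, "|", fixed = TRUE)[[1]]
  }))
  prep %in% subcats
}
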