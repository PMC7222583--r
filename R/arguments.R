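# Relational analysis, part 2: argument identification for detected trigger
# instances, argument-reuse licensing, coordination distribution, negation,
# sortal-anaphora incorporation, and sentence-level inference.
#
# Argument search is nearest-first: candidate NPs are scanned outward from
# the indicator in the licensed direction, and the first (object, subject)
# pair whose semantic-type combination is licensed by the ontology wins.
# When the forward orientation is unlicensed but the rule allows inversion
# and the transposed triple is licensed, semantic roles are bound per the
# ontology triple rather than surface order.

new_arg_context <- function(sent) {
  env <- new.env(parent = emptyenv())
  env$used <- vector("list", length(sent$phrases))   # per phrase: indicator phrase idx vector
  env$consumed_pps <- integer()                      # cue-consumed PP phrase indices
  env$preds <- list()
  env
}

mark_used <- function(ctx, phrase_idx, indicator_phrase) {
  if (is.na(phrase_idx)) return(invisible())
  ctx$used[[phrase_idx]] <- c(ctx$used[[phrase_idx]], indicator_phrase)
  invisible()
}

# Argument-reuse licensing: a phrase already bound as an argument may be
# reused only when (a) it immediately precedes an overt relativizer, (b) it
# immediately precedes a PP whose predication already took it as an argument
# (reduced relative clause head), or (c) the current indicator is the PP
# immediately following it.
reuse_allowed <- function(ctx, sent, phrase_idx, inst, kb) {
  uses <- ctx$used[[phrase_idx]]
  if (is.null(uses) || !length(uses)) return(TRUE)
  tokens <- sent$tokens
  ph <- sent$phrases[[phrase_idx]]
  nt <- ph$last + 1L
  if (nt <= nrow(tokens) && tokens$text[nt] == ",") nt <- nt + 1L
  if (nt <= nrow(tokens) &&
      tolower(tokens$text[nt]) %in% kb$word_lists$relativizers) {
    return(TRUE)  # (a) head of an overt relative clause
  }
  nxt <- next_matching(sent$phrases, phrase_idx, function(p) p$kind != "PUNCT")
  if (!is.na(nxt) && sent$phrases[[nxt]]$kind == "PP") {
    if (!is.na(inst$phrase) && nxt == inst$phrase) return(TRUE)  # (c)
    if (nxt %in% uses) return(TRUE)                              # (b)
  }
  FALSE
}

# mapped-phrase candidate lists around an anchor phrase
mapped_phrases_before <- function(sent, anchor) {
  idx <- rev(seq_len(anchor - 1L))
  idx[vapply(idx, function(q) {
    sent$phrases[[q]]$kind %in% c("NP", "PP") &&
      !is.null(phrase_best_mapping(sent$phrases[[q]]))
  }, logical(1))]
}

mapped_phrases_after <- function(sent, anchor) {
  idx <- seq(anchor + 1L, length.out = max(0L, length(sent$phrases) - anchor))
  idx[vapply(idx, function(q) {
    sent$phrases[[q]]$kind %in% c("NP", "PP") &&
      !is.null(phrase_best_mapping(sent$phrases[[q]]))
  }, logical(1))]
}

pp_candidates <- function(sent, anchor, prep, direction = "after") {
  cands <- if (direction == "after") mapped_phrases_after(sent, anchor)
           else mapped_phrases_before(sent, anchor)
  cands[vapply(cands, function(q) {
    ph <- sent$phrases[[q]]
    ph$kind == "PP" && !is.na(ph$prep) && sent$tokens$lemma[ph$prep] == tolower(prep)
  }, logical(1))]
}

# consecutive PP phrases directly following a trigger phrase
pp_chain_after <- function(sent, anchor) {
  out <- integer()
  q <- anchor + 1L
  while (q <= length(sent$phrases) && sent$phrases[[q]]$kind == "PP") {
    out <- c(out, q)
    q <- q + 1L
  }
  out
}

#' Identify arguments for a trigger instance
#'
#' Applies the class-specific syntactic rules (verbal, prepositional,
#' nominal, adjectival, structural), the argument-reuse constraint, the
#' conjunct ban (subject and object of one predication may not be conjuncts
#' of the same coordination unless the rule cue is between-and), and
#' ontology licensing, and emits zero or more predications into the
#' extraction context (coordination distribution included).
#'
#' @param inst an indicator instance from [detect_triggers()].
#' @param sent the annotated sentence.
#' @param kb a `predication_kb`.
#' @param ctx extraction context from the pipeline (created when NULL).
#' @return list of predications emitted for this instance.
#' @export
identify_arguments <- function(inst, sent, kb, ctx = NULL) {
  if (is.null(ctx)) ctx <- new_arg_context(sent)
  n0 <- length(ctx$preds)
  switch(inst$class,
    verb = identify_verbal(inst, sent, kb, ctx),
    adj = identify_adjectival(inst, sent, kb, ctx),
    noun = identify_nominal(inst, sent, kb, ctx),
    prep = identify_prepositional(inst, sent, kb, ctx),
    mod_head = identify_mod_head(inst, sent, kb, ctx))
  if (length(ctx$preds) > n0) ctx$preds[(n0 + 1L):length(ctx$preds)] else list()
}

# try (subject candidates x object candidates) nearest-first; returns TRUE
# when a predication was emitted
bind_pair <- function(inst, sent, kb, ctx, subj_cands, obj_cands,
                      cue_pp = NA_integer_) {
  rule <- inst$rule
  for (op in obj_cands) {
    for (sp in subj_cands) {
      if (identical(sp, op)) next
      if (!reuse_allowed(ctx, sent, sp, inst, kb) ||
          !reuse_allowed(ctx, sent, op, inst, kb)) next
      ck_s <- coordination_of(sent$coordinations, sp)
      ck_o <- coordination_of(sent$coordinations, op)
      if (!is.na(ck_s) && identical(ck_s, ck_o) &&
          !identical(rule$cue_word, "BETWEEN_AND")) next
      sm <- phrase_best_mapping(sent$phrases[[sp]])
      om <- phrase_best_mapping(sent$phrases[[op]])
      ori <- licensed_orientations(sm$semtypes, rule$predicate, om$semtypes,
                                   kb, allow_inverse = isTRUE(rule$inverse))
      if ("FORWARD" %in% ori) {
        emit_predication(inst, sent, kb, ctx, sp, sm, op, om, cue_pp)
        return(TRUE)
      }
      if ("INVERSE" %in% ori) {
        emit_predication(inst, sent, kb, ctx, op, om, sp, sm, cue_pp)
        return(TRUE)
      }
    }
  }
  FALSE
}

emit_predication <- function(inst, sent, kb, ctx, sp, sm, op, om, cue_pp) {
  rule <- inst$rule
  pred <- new_predication(
    subj = sm, obj = om, predicate = base_predicate(rule$predicate),
    negated = isTRUE(rule$implicit_negative),
    sentence = sent$index, subj_phrase = sp, obj_phrase = op,
    indicator_type = inst$class,
    indicator_text = span_text(sent$text, sent$tokens, inst$tok, inst$tok_end),
    indicator_tok = inst$tok, rule = rule)
  ctx$preds[[length(ctx$preds) + 1L]] <- pred
  mark_used(ctx, sp, inst$phrase)
  mark_used(ctx, op, inst$phrase)
  if (!is.na(cue_pp)) ctx$consumed_pps <- c(ctx$consumed_pps, cue_pp)
  distribute_over_coordination(inst, sent, kb, ctx, pred)
}

# coordination license for argument reuse: when a conjunct is an argument,
# emit parallel predications for every other conjunct in the same role,
# subject to ontology licensing
distribute_over_coordination <- function(inst, sent, kb, ctx, pred) {
  for (role in c("subj", "obj")) {
    p <- if (role == "subj") pred$subj_phrase else pred$obj_phrase
    ck <- coordination_of(sent$coordinations, p)
    if (is.na(ck)) next
    other_m <- if (role == "subj") pred$obj else pred$subj
    for (q in sent$coordinations[[ck]]$conjuncts) {
      if (q == p) next
      qm <- phrase_best_mapping(sent$phrases[[q]])
      if (is.null(qm)) next
      st <- if (role == "subj") qm$semtypes else other_m$semtypes
      ot <- if (role == "subj") other_m$semtypes else qm$semtypes
      if (!"FORWARD" %in% licensed_orientations(st, pred$predicate, ot, kb)) next
      clone <- pred
      if (role == "subj") { clone$subj <- qm; clone$subj_phrase <- q }
      else { clone$obj <- qm; clone$obj_phrase <- q }
      if (any(vapply(ctx$preds, function(x) predication_key(x) == predication_key(clone),
                     logical(1)))) next
      ctx$preds[[length(ctx$preds) + 1L]] <- clone
      mark_used(ctx, q, inst$phrase)
    }
  }
}

identify_verbal <- function(inst, sent, kb, ctx) {
  rule <- inst$rule
  anchor <- inst$phrase
  left <- mapped_phrases_before(sent, anchor)
  right_anchor <- anchor
  # brace/phrase rules anchor the postverbal search after the last trigger token
  if (inst$tok_end > sent$phrases[[anchor]]$last) {
    right_anchor <- which(vapply(sent$phrases, function(p)
      p$first <= inst$tok_end && p$last >= inst$tok_end, logical(1)))[1]
  }
  right <- mapped_phrases_after(sent, right_anchor)
  subj_side <- if (inst$passive) right else left
  obj_side <- if (inst$passive) left else right
  cue_pp <- NA_integer_
  if (!is.na(rule$cue_role) && !identical(rule$cue_word, "BETWEEN_AND")) {
    cued <- c(pp_candidates(sent, right_anchor, rule$cue_word, "after"),
              pp_candidates(sent, anchor, rule$cue_word, "before"))
    if (!length(cued)) return(invisible(FALSE))
    if (rule$cue_role == "subject") {
      # the cued subject occupies a postverbal PP; the remaining argument
      # is sought on the opposite (preverbal) side first
      for (cp in cued) {
        obj_cands <- if (cp %in% right) left else right
        if (bind_pair(inst, sent, kb, ctx, cp, obj_cands, cue_pp = cp)) {
          return(invisible(TRUE))
        }
      }
      return(invisible(FALSE))
    }
    for (cp in cued) {
      subj_cands <- if (cp %in% right) left else right
      if (bind_pair(inst, sent, kb, ctx, subj_cands, cp, cue_pp = cp)) {
        return(invisible(TRUE))
      }
    }
    return(invisible(FALSE))
  }
  invisible(bind_pair(inst, sent, kb, ctx, subj_side, obj_side))
}

identify_prepositional <- function(inst, sent, kb, ctx) {
  if (inst$phrase %in% ctx$consumed_pps) return(invisible(FALSE))
  prep <- sent$tokens$lemma[inst$tok]
  obj_cands <- if (!is.null(phrase_best_mapping(sent$phrases[[inst$phrase]]))) {
    inst$phrase
  } else integer()
  if (!length(obj_cands)) return(invisible(FALSE))
  if (prep %in% c("of", "for", "from", "with")) {
    before <- prev_matching(sent$phrases, inst$phrase,
                            function(p) p$kind %in% c("NP", "PP"))
    if (is.na(before) || before != inst$phrase - 1L) return(invisible(FALSE))
    if (is.null(phrase_best_mapping(sent$phrases[[before]]))) return(invisible(FALSE))
    subj_cands <- before
  } else {
    subj_cands <- mapped_phrases_before(sent, inst$phrase)
  }
  invisible(bind_pair(inst, sent, kb, ctx, subj_cands, obj_cands))
}

identify_nominal <- function(inst, sent, kb, ctx) {
  rule <- inst$rule
  anchor <- if (!is.na(inst$phrase)) inst$phrase else return(invisible(FALSE))
  chain <- pp_chain_after(sent, anchor)
  chain <- chain[vapply(chain, function(q)
    !is.null(phrase_best_mapping(sent$phrases[[q]])), logical(1))]
  chain_prep <- vapply(chain, function(q)
    sent$tokens$lemma[sent$phrases[[q]]$prep], "")
  # object candidates
  if (!is.na(rule$cue_role) && rule$cue_role == "object") {
    k <- which(chain_prep == tolower(rule$cue_word))
    if (!length(k)) return(invisible(FALSE))
    obj_cands <- chain[seq(k[1], length(chain))]
    obj_cue_pp <- chain[k[1]]
  } else {
    k <- which(chain_prep == "of")
    obj_cands <- if (length(k)) chain[seq(k[1], length(chain))] else integer()
    obj_cue_pp <- if (length(k)) chain[k[1]] else NA_integer_
  }
  mod_cands <- integer()  # arguments realized as modifiers of the trigger NP
  tp <- sent$phrases[[anchor]]
  mod_maps <- Filter(function(m) m$end_tok < inst$tok, tp$mappings)
  has_mods <- length(mod_maps) > 0
  # subject candidates
  cued_subj <- integer()
  if (!is.na(rule$cue_role) && rule$cue_role == "subject") {
    cued_subj <- chain[chain_prep == tolower(rule$cue_word)]
  }
  obligatory_obj <- !is.na(rule$cue_role) && rule$cue_role == "object"
  nonprep <- tolower(rule$lexeme) %in% kb$word_lists$nonprep_subject_nouns
  fallback_subj <- integer()
  if (obligatory_obj && !nonprep) {
    fallback_subj <- chain[chain_prep == "of"]  # of as subject cue
  }
  fallback_subj <- c(fallback_subj, nominal_left_subjects(sent, anchor))
  if (nonprep) {
    fallback_subj <- fallback_subj[!vapply(fallback_subj, function(q)
      sent$phrases[[q]]$kind == "PP", logical(1))]
  }
  try_subjects <- function(subjs, cue_pp) {
    length(subjs) > 0 && length(obj_cands) > 0 &&
      bind_pair(inst, sent, kb, ctx, subjs, obj_cands, cue_pp = cue_pp)
  }
  if (length(cued_subj)) {
    for (cp in cued_subj) {
      if (try_subjects(cp, cp)) return(invisible(TRUE))
    }
  }
  if (try_subjects(fallback_subj, obj_cue_pp)) return(invisible(TRUE))
  # modifier arguments (e.g. "surgical fracture treatment")
  if (has_mods && length(obj_cands)) {
    for (mm in rev(mod_maps)) {
      for (op in obj_cands) {
        om <- phrase_best_mapping(sent$phrases[[op]])
        if ("FORWARD" %in% licensed_orientations(mm$semtypes, rule$predicate,
                                                 om$semtypes, kb)) {
          emit_predication(inst, sent, kb, ctx, anchor, mm, op, om, obj_cue_pp)
          return(invisible(TRUE))
        }
      }
    }
  }
  invisible(FALSE)
}

# leftward subject scan for nominal triggers: crossing is allowed over
# punctuation, adjectival/other chunks, NPs/PPs, and BE verbs; a non-BE
# verb, conjunction, or complementizer blocks the search
nominal_left_subjects <- function(sent, anchor) {
  out <- integer()
  for (q in rev(seq_len(anchor - 1L))) {
    ph <- sent$phrases[[q]]
    if (ph$kind == "VERB") {
      tok <- ph$first
      if (has_feature(sent$tokens$features[tok], "be", "1") ||
          sent$tokens$pos[tok] %in% c("aux", "modal")) next
      break
    }
    if (ph$kind %in% c("CONJ", "COMPL")) break
    if (ph$kind %in% c("NP", "PP") && !is.null(phrase_best_mapping(ph))) {
      out <- c(out, q)
    }
  }
  out
}

identify_adjectival <- function(inst, sent, kb, ctx) {
  tokens <- sent$tokens
  a <- inst$tok
  ph <- sent$phrases[[inst$phrase]]
  hyphenated <- a - 1L >= ph$first && tokens$text[a - 1L] == "-"
  if (hyphenated) {
    left_maps <- Filter(function(m) m$end_tok < a - 1L, ph$mappings)
    right_maps <- Filter(function(m) m$start_tok > a, ph$mappings)
    if (length(left_maps) && length(right_maps)) {
      left_maps <- order_mappings(left_maps)
      right_maps <- order_mappings(right_maps)
      for (sm in left_maps) {
        for (om in right_maps) {
          if ("FORWARD" %in% licensed_orientations(sm$semtypes, inst$rule$predicate,
                                                   om$semtypes, kb)) {
            emit_predication(inst, sent, kb, ctx, inst$phrase, sm, inst$phrase, om,
                             NA_integer_)
            return(invisible(TRUE))
          }
        }
      }
    }
    return(invisible(FALSE))
  }
  invisible(bind_pair(inst, sent, kb, ctx,
                      mapped_phrases_before(sent, inst$phrase),
                      mapped_phrases_after(sent, inst$phrase)))
}

identify_mod_head <- function(inst, sent, kb, ctx) {
  ph <- sent$phrases[[inst$phrase]]
  hm <- Filter(function(m) m$start_tok <= ph$head & m$end_tok >= ph$head,
               ph$mappings)
  if (!length(hm)) return(invisible(FALSE))
  hm <- order_mappings(hm)[[1]]
  mods <- order_mappings(Filter(function(m) m$end_tok < hm$start_tok, ph$mappings))
  for (mm in mods) {
    if ("FORWARD" %in% licensed_orientations(mm$semtypes, inst$rule$predicate,
                                             hm$semtypes, kb)) {
      emit_predication(inst, sent, kb, ctx, inst$phrase, mm, inst$phrase, hm,
                       NA_integer_)
      return(invisible(TRUE))
    }
  }
  invisible(FALSE)
}

#' Apply negation to extracted predications
#'
#' A predication is negated when one of its arguments carries a negated
#' mention flag, when its indicator is in the scope of a textual negation
#' trigger (the indicator immediately follows the trigger, or the
#' intervening tokens are adverbs or part of a verbal complex), or -- for
#' modifier-head predications -- when the modifier bears a `non-` prefix.
#' Pseudo-negation patterns are exempt. Implicit-negative indicator rules
#' flip back to the positive predicate under textual negation; double
#' negation is never emitted.
#'
#' @param preds list of predications for one sentence.
#' @param sent the annotated sentence.
#' @param kb a `predication_kb`.
#' @return the predications with `negated` flags resolved.
#' @export
negate_predications <- function(preds, sent, kb) {
  if (!length(preds)) return(preds)
  trig <- kb$word_lists$negation_triggers
  occ <- find_phrase_occurrences(sent$tokens, trig$trigger)
  if (nrow(occ)) {
    occ$direction <- trig$direction[occ$which]
    pseudo <- find_phrase_occurrences(sent$tokens, kb$word_lists$pseudo_negation)
    if (nrow(pseudo)) occ <- occ[!occ$start %in% pseudo$start, , drop = FALSE]
  }
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    if (p$inferred || p$predicate %in% c("ISA", COMPARATIVE_PREDICATES)) next
    textual <- FALSE
    if (isTRUE(p$subj$negated) || isTRUE(p$obj$negated)) textual <- TRUE
    if (!textual && identical(p$indicator_type, "mod_head")) {
      textual <- modifier_non_prefixed(sent$tokens, p$subj$start_tok)
    } else if (!textual && !is.na(p$indicator_tok) && nrow(occ)) {
      for (k in seq_len(nrow(occ))) {
        if (occ$direction[k] != "pre" || occ$end[k] >= p$indicator_tok) next
        between <- seq(occ$end[k] + 1L, length.out = p$indicator_tok - occ$end[k] - 1L)
        if (!length(between) ||
            all(sent$tokens$pos[between] %in% c("adv", "aux", "modal", "verb"))) {
          textual <- TRUE
          break
        }
      }
    }
    if (textual) preds[[i]]$negated <- !p$negated
  }
  preds
}

modifier_non_prefixed <- function(tokens, start_tok) {
  if (grepl("^non-", tolower(tokens$text[start_tok]))) return(TRUE)
  start_tok >= 3L && tolower(tokens$text[start_tok - 2L]) == "non" &&
    tokens$text[start_tok - 1L] == "-"
}

#' Incorporate sortal anaphora into predications
#'
#' A predication with an anaphoric argument is replaced by one predication
#' per antecedent (set-membership anaphora multiplies), with the antecedent
#' concept in the same argument position and both sentence ids recorded.
#' Replacements that would violate ontology licensing keep the original
#' predication instead.
#'
#' @param preds list of predications (document level).
#' @param links anaphor links from [resolve_sortal_anaphora()].
#' @param doc_sentences the annotated sentences.
#' @param kb a `predication_kb`.
#' @return the updated predication list.
#' @export
substitute_anaphora <- function(preds, links, doc_sentences, kb) {
  if (!length(links) || !length(preds)) return(preds)
  out <- list()
  for (p in preds) {
    link_s <- find_link(links, p$sentence, p$subj_phrase)
    link_o <- find_link(links, p$sentence, p$obj_phrase)
    link <- link_s %||% link_o
    if (is.null(link) || p$predicate %in% c("ISA", COMPARATIVE_PREDICATES)) {
      out[[length(out) + 1L]] <- p
      next
    }
    role <- if (!is.null(link_s)) "subj" else "obj"
    repls <- list()
    for (a in link$antecedents) {
      am <- phrase_best_mapping(doc_sentences[[a[1]]]$phrases[[a[2]]])
      if (is.null(am)) next
      st <- if (role == "subj") am$semtypes else p$subj$semtypes
      ot <- if (role == "subj") p$obj$semtypes else am$semtypes
      if (!"FORWARD" %in% licensed_orientations(st, p$predicate, ot, kb)) next
      q <- p
      if (role == "subj") { q$subj <- am; q$subj_phrase <- a[2] }
      else { q$obj <- am; q$obj_phrase <- a[2] }
      q$sentence2 <- a[1]
      repls[[length(repls) + 1L]] <- q
    }
    if (length(repls)) out <- c(out, repls) else out[[length(out) + 1L]] <- p
  }
  out
}

find_link <- function(links, sentence, phrase) {
  if (is.na(phrase)) return(NULL)
  for (l in links) {
    if (l$anaphor[1] == sentence && l$anaphor[2] == phrase) return(l)
  }
  NULL
}

#' Apply sentence-level inference rules
#'
#' Inference rules combine two predications into a more specific conclusion
#' (`IF <X-TREATS-Y AND Z-PROCESS_OF-Y> THEN <X-TREATS-Z>`), applied at the
#' sentence level with fixpoint iteration and deduplication. Conclusions
#' must be ontology-licensed and are flagged inferred. Predications produced
#' by anaphora substitution participate via their extraction sentence.
#'
#' @param preds list of predications (document level).
#' @param kb a `predication_kb`.
#' @return the predications with inferred additions appended.
#' @export
infer_predications <- function(preds, kb) {
  rules <- kb$inference_rules
  if (!nrow(rules) || !length(preds)) return(preds)
  sentences <- unique(vapply(preds, `[[`, 0L, "sentence"))
  for (s in sentences) {
    repeat {
      pool <- Filter(function(p) p$sentence == s && !p$negated, preds)
      keys <- vapply(preds, predication_key, "")
      added <- FALSE
      for (r in seq_len(nrow(rules))) {
        rule <- rules[r, ]
        for (p1 in pool) {
          if (p1$predicate != rule$p1p) next
          for (p2 in pool) {
            if (p2$predicate != rule$p2p) next
            b <- bind_inference(rule, p1, p2)
            if (is.null(b)) next
            concl <- new_predication(
              subj = b[[rule$cs]], obj = b[[rule$co]], predicate = rule$cp,
              sentence = s, inferred = TRUE, indicator_type = "inference")
            if (!"FORWARD" %in% licensed_orientations(
              concl$subj$semtypes, concl$predicate, concl$obj$semtypes, kb)) next
            if (predication_key(concl) %in% keys) next
            preds[[length(preds) + 1L]] <- concl
            keys <- c(keys, predication_key(concl))
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
  }
  preds
}

# consistent variable binding for premise pair; returns var -> mapping
bind_inference <- function(rule, p1, p2) {
  b <- list()
  assign_var <- function(b, v, m) {
    if (!is.null(b[[v]]) && b[[v]]$concept_id != m$concept_id) return(NULL)
    b[[v]] <- m
    b
  }
  b <- assign_var(b, rule$p1s, p1$subj); if (is.null(b)) return(NULL)
  b <- assign_var(b, rule$p1o, p1$obj); if (is.null(b)) return(NULL)
  b <- assign_var(b, rule$p2s, p2$subj); if (is.null(b)) return(NULL)
  b <- assign_var(b, rule$p2o, p2$obj); if (is.null(b)) return(NULL)
  b
}
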