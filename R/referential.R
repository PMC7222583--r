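# Referential analysis: mapping noun phrases to dictionary concepts
# (longest-match with dysonym suppression and a pluggable same-span
# disambiguation hook), exact-match gene alias lookup, abbreviation
# inheritance, and NegEx-style negated-mention flagging.

new_mapping <- function(concept_id, name, semtypes, source, start_tok, end_tok,
                        start, end, covers_head, score, synonym) {
  list(concept_id = concept_id, name = name, semtypes = semtypes,
       source = source, start_tok = start_tok, end_tok = end_tok,
       start = start, end = end, covers_head = covers_head,
       negated = FALSE, score = score, synonym = synonym)
}

phrase_content_tokens <- function(tokens, phrase) {
  idx <- phrase$first:phrase$last
  idx <- setdiff(idx, phrase$prep)
  idx[!tokens$is_punct[idx] &
        !tokens$pos[idx] %in% c("det", "num", "adv", "punct")]
}

#' Map a phrase to dictionary concepts
#'
#' Longest-span dictionary matches over the phrase's tokens
#' (inflection-normalized), longest-first then leftmost; dysonym-suppressed
#' synonyms are excluded when the index is built; overlapping candidates are
#' resolved in favour of the span already covered; remaining same-span ties
#' are broken by a pluggable disambiguation hook (default: lexicographic
#' concept id).
#'
#' @param phrase a phrase from [chunk_phrases()].
#' @param tokens the sentence tokens.
#' @param sentence the sentence text.
#' @param kb a `predication_kb`.
#' @param extra_index optional named list `surface -> concept ids` consulted
#'   in addition to the dictionary (used for registered abbreviations).
#' @param disambiguator optional `function(concept_ids, kb)` returning one
#'   id among same-span candidates.
#' @return list of concept mappings (possibly empty).
#' @export
map_concepts <- function(phrase, tokens, sentence, kb, extra_index = NULL,
                         disambiguator = NULL) {
  if (!phrase$kind %in% c("NP", "PP")) return(list())
  content <- phrase_content_tokens(tokens, phrase)
  if (!length(content)) return(list())
  idx <- setdiff(phrase$first:phrase$last, phrase$prep)
  idx <- idx[!tokens$pos[idx] %in% c("det")]
  lo <- min(idx); hi <- max(idx)
  spans <- list()
  for (len in rev(seq_len(hi - lo + 1L))) {
    for (i in lo:(hi - len + 1L)) {
      j <- i + len - 1L
      if (tokens$is_punct[i] || tokens$is_punct[j]) next
      spans[[length(spans) + 1L]] <- c(i, j)
    }
  }
  covered <- logical(nrow(tokens))
  out <- list()
  for (sp in spans) {
    if (any(covered[sp[1]:sp[2]])) next
    keys <- span_lookup_keys(sentence, tokens, sp[1], sp[2])
    ids <- character()
    for (key in keys) {
      ids <- c(ids, kb$syn_index[[key]] %||% character(),
               extra_index[[key]] %||% character())
      if (length(ids)) break
    }
    ids <- unique(ids)
    if (!length(ids)) next
    id <- if (length(ids) == 1L) ids else if (!is.null(disambiguator)) {
      disambiguator(ids, kb)
    } else sort(ids)[1]
    row <- kb$concept_by_id[[id]]
    if (is.null(row) || is.na(row)) next
    covered[sp[1]:sp[2]] <- TRUE
    score <- as.integer(round(1000 * length(intersect(sp[1]:sp[2], content)) /
                                length(content)))
    out[[length(out) + 1L]] <- new_mapping(
      concept_id = id, name = kb$concepts$name[row],
      semtypes = concept_types(kb, id), source = kb$concepts$source[row],
      start_tok = sp[1], end_tok = sp[2],
      start = tokens$start[sp[1]], end = tokens$end[sp[2]],
      covers_head = !is.na(phrase$head) && phrase$head >= sp[1] && phrase$head <= sp[2],
      score = score, synonym = span_text(sentence, tokens, sp[1], sp[2]))
  }
  out
}

span_lookup_keys <- function(sentence, tokens, i, j, lemma = NULL) {
  raw <- normalize_surface(span_text(sentence, tokens, i, j))
  keys <- raw
  # inflection normalization: strip plural from the final word
  words <- strsplit(raw, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  variants <- character()
  if (has_feature(tokens$features[j], "number", "plural") &&
      nzchar(tokens$lemma[j])) {
    variants <- tokens$lemma[j]
  }
  if (grepl("ies$", last)) variants <- c(variants, sub("ies$", "y", last))
  if (grepl("es$", last)) variants <- c(variants, sub("es$", "", last), sub("s$", "", last))
  if (grepl("[a-z]s$", last)) variants <- c(variants, sub("s$", "", last))
  for (v in unique(variants)) {
    if (!identical(v, last)) {
      keys <- c(keys, paste(c(words[-length(words)], v), collapse = " "))
    }
  }
  unique(keys)
}

#' Map gene/protein mentions via the gene alias index
#'
#' Exact matching (case-normalized) between token spans of the phrase and
#' gene aliases. A mention may map to several genes; all are kept, with the
#' semantic type Gene or Genome. Gene mappings never suppress dictionary
#' mappings (both coexist).
#'
#' @inheritParams map_concepts
#' @return list of GENE-source mappings.
#' @export
map_genes <- function(phrase, tokens, sentence, kb) {
  if (!phrase$kind %in% c("NP", "PP")) return(list())
  content <- phrase_content_tokens(tokens, phrase)
  if (!length(content) || !nrow(kb$gene_index_norm)) return(list())
  idx <- setdiff(phrase$first:phrase$last, phrase$prep)
  idx <- idx[!tokens$pos[idx] %in% c("det")]
  lo <- min(idx); hi <- max(idx)
  out <- list()
  covered <- logical(nrow(tokens))
  for (len in rev(seq_len(hi - lo + 1L))) {
    for (i in lo:(hi - len + 1L)) {
      j <- i + len - 1L
      if (tokens$is_punct[i] || tokens$is_punct[j]) next
      if (any(covered[i:j])) next
      key <- normalize_surface(span_text(sentence, tokens, i, j))
      rows <- kb$gene_lookup[[key]]
      if (is.null(rows)) next
      covered[i:j] <- TRUE
      score <- as.integer(round(1000 * length(intersect(i:j, content)) /
                                  length(content)))
      for (r in rows) {
        gi <- kb$gene_index_norm[r, ]
        out[[length(out) + 1L]] <- new_mapping(
          concept_id = gi$gene_id, name = gi$symbol,
          semtypes = "Gene or Genome", source = "GENE",
          start_tok = i, end_tok = j,
          start = tokens$start[i], end = tokens$end[j],
          covers_head = !is.na(phrase$head) && phrase$head >= i && phrase$head <= j,
          score = score, synonym = span_text(sentence, tokens, i, j))
      }
    }
  }
  out
}

# order mappings within a phrase: deterministic (position, then score desc,
# then source preference, then id)
order_mappings <- function(mappings) {
  if (!length(mappings)) return(mappings)
  key <- vapply(mappings, function(m) {
    sprintf("%04d-%04d-%s-%s", m$start_tok, 9999L - m$score,
            if (m$source == "GENE") "1" else "0", m$concept_id)
  }, "")
  mappings[order(key)]
}

# best mapping for the phrase's semantic head
phrase_best_mapping <- function(phrase) {
  cand <- Filter(function(m) {
    !is.na(phrase$sem_head) &&
      m$start_tok <= phrase$sem_head && m$end_tok >= phrase$sem_head
  }, phrase$mappings)
  if (!length(cand)) return(NULL)
  key <- vapply(cand, function(m) {
    sprintf("%04d-%s-%s", 9999L - m$score,
            if (m$source == "GENE") "1" else "0", m$concept_id)
  }, "")
  cand[[order(key)[1]]]
}

#' Flag negated concept mentions
#'
#' NegEx-style processing with a narrow window: the concept mentions
#' following a pre-position negation trigger (or preceding a post-position
#' trigger such as "absent") within a window of 2 concepts are flagged
#' negated, for all semantic types. Pseudo-negation patterns ("not only",
#' "no more than", ...) are exempt.
#'
#' @param phrases phrase list whose `mappings` are filled.
#' @param tokens the sentence tokens.
#' @param word_lists the knowledge-base word lists.
#' @return the phrase list with mention `negated` flags set.
#' @export
detect_negated_mentions <- function(phrases, tokens, word_lists) {
  trig <- word_lists$negation_triggers
  occ <- find_phrase_occurrences(tokens, trig$trigger)
  if (!nrow(occ)) return(phrases)
  occ$direction <- trig$direction[occ$which]
  pseudo <- find_phrase_occurrences(tokens, word_lists$pseudo_negation)
  reg <- list()
  for (p in seq_along(phrases)) {
    for (m in seq_along(phrases[[p]]$mappings)) {
      mp <- phrases[[p]]$mappings[[m]]
      reg[[length(reg) + 1L]] <- list(p = p, m = m, start_tok = mp$start_tok)
    }
  }
  if (!length(reg)) return(phrases)
  reg <- reg[order(vapply(reg, `[[`, 0L, "start_tok"))]
  boundary <- which(tokens$text %in% c(";", ":", ".", "(", ")") |
                      tolower(tokens$text) == "but")
  in_scope <- function(trig_from, trig_to, mention_tok) {
    lo <- min(trig_from, mention_tok); hi <- max(trig_to, mention_tok)
    !any(boundary > lo & boundary < hi)
  }
  for (k in seq_len(nrow(occ))) {
    if (nrow(pseudo) && any(pseudo$start == occ$start[k])) next
    if (occ$direction[k] == "pre") {
      after <- Filter(function(r) r$start_tok > occ$end[k] &&
                        in_scope(occ$start[k], occ$end[k], r$start_tok), reg)
      hit <- utils::head(after, 2L)
    } else {
      before <- Filter(function(r) r$start_tok < occ$start[k] &&
                         in_scope(occ$start[k], occ$end[k], r$start_tok), reg)
      hit <- utils::tail(before, 2L)
    }
    for (r in hit) phrases[[r$p]]$mappings[[r$m]]$negated <- TRUE
  }
  phrases
}

# occurrences of (possibly multi-word) lower-case phrases in the token stream
find_phrase_occurrences <- function(tokens, phrases_lc) {
  lower <- tolower(tokens$text)
  out <- data.frame(start = integer(), end = integer(), which = integer())
  for (w in seq_along(phrases_lc)) {
    words <- strsplit(phrases_lc[w], " ", fixed = TRUE)[[1]]
    k <- length(words)
    if (nrow(tokens) < k) next
    for (i in seq_len(nrow(tokens) - k + 1L)) {
      if (all(lower[i:(i + k - 1L)] == words)) {
        out <- rbind(out, data.frame(start = i, end = i + k - 1L, which = w))
      }
    }
  }
  out[order(out$start), , drop = FALSE]
}
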