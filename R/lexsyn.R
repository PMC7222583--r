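# Lexical/syntactic analysis: lexicon lookup, part-of-speech disambiguation
# (with a pluggable tagger hook), and the minimal-commitment shallow parser.
#
# The parser is built on barrier words: verbs, auxiliaries, modals,
# prepositions, conjunctions, and complementizers open a new phrase and
# close the preceding one. Any chunk containing a noun is a simple NP; an NP
# whose first element is a preposition is a PP; the right-most noun is the
# head and all other items except determiners (and punctuation, adverbs,
# numerals) are modifiers.

BUILTIN_CLOSED_CLASS <- list(
  det = c("the", "a", "an", "this", "these", "those", "such", "both",
          "either", "each", "every", "all", "some", "any", "several",
          "its", "their", "his", "her", "our", "your", "my", "no"),
  prep = c("of", "in", "on", "for", "with", "to", "from", "by", "at",
           "against", "between", "among", "via", "during", "after", "before",
           "under", "over", "within", "without", "into", "through", "as",
           "per", "than", "like"),
  conj = c("and", "or", "but", "nor"),
  modal = c("can", "could", "may", "might", "will", "would", "shall",
            "should", "must"),
  compl = c("that", "which", "who", "whom", "whose", "whether", "because",
            "although", "while", "since", "if", "when", "where"),
  pron = c("it", "they", "we", "he", "she", "i", "you", "them", "him", "us")
)

MULTIWORD_CONJUNCTIONS <- list(c("followed", "by"), c("in", "combination", "with"),
                               c("but", "not"), c("as", "well", "as"))
APPOSITIVE_MARKERS <- list(c("such", "as"))

#' Look up tokens in the lexicon
#'
#' Longest-match, leftmost-first lookup of (possibly multi-token) surface
#' forms against the knowledge base lexicon plus a built-in closed-class
#' inventory. Every matched span carries all homonymous records; unmatched
#' alphabetic tokens receive a default open-class record by suffix
#' heuristics (`-ly` adverb, otherwise noun), numeric tokens a numeral
#' record, punctuation a punct record.
#'
#' @param tokens token data.frame from [tokenize()].
#' @param kb a `predication_kb` (its `lexicon` component is used).
#' @return the token data.frame with added columns `lemma`, `cats`
#'   (`;`-joined candidate categories), `features` (from the matched
#'   records), `unit` (multi-token lexical unit id, NA for single tokens).
#' @export
lexicon_lookup <- function(tokens, kb) {
  n <- nrow(tokens)
  tokens$lemma <- tolower(tokens$text)
  tokens$cats <- NA_character_
  tokens$features <- ""
  tokens$unit <- NA_integer_
  if (!n) return(tokens)
  lex <- kb$lexicon_norm
  idx <- kb$lex_index
  max_len <- max(c(1L, lengths(strsplit(names(idx) %||% character(), " "))))
  i <- 1L; unit <- 0L
  while (i <= n) {
    if (tokens$is_punct[i]) {
      tokens$cats[i] <- "punct"; tokens$lemma[i] <- tokens$text[i]
      i <- i + 1L; next
    }
    hit_len <- 0L; hit_rows <- NULL
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      span <- i:(i + len - 1L)
      if (any(tokens$is_punct[span] & !tokens$text[span] %in% "-")) next
      key <- normalize_surface(paste(tokens$text[span], collapse = " "))
      rows <- idx[[key]]
      if (!is.null(rows)) { hit_len <- len; hit_rows <- rows; break }
    }
    if (hit_len > 0L) {
      span <- i:(i + hit_len - 1L)
      recs <- lex[hit_rows, , drop = FALSE]
      cats <- paste(unique(recs$cat), collapse = ";")
      feats <- paste(recs$features[nzchar(recs$features)], collapse = ";")
      if (hit_len > 1L) {
        unit <- unit + 1L
        tokens$unit[span] <- unit
      }
      tokens$cats[span] <- cats
      tokens$lemma[span] <- recs$base[1]
      tokens$features[span] <- feats
      i <- i + hit_len
      next
    }
    w <- tolower(tokens$text[i])
    cc <- names(BUILTIN_CLOSED_CLASS)[vapply(BUILTIN_CLOSED_CLASS,
                                             function(v) w %in% v, logical(1))]
    if (length(cc)) {
      tokens$cats[i] <- paste(cc, collapse = ";")
    } else if (grepl("^[0-9][0-9.,]*$", w)) {
      tokens$cats[i] <- "num"
    } else if (grepl("ly$", w) && nchar(w) > 3) {
      tokens$cats[i] <- "adv"
    } else {
      tokens$cats[i] <- "noun"
      # bare plural heuristic for out-of-lexicon nouns
      if (grepl("[a-z]s$", w) && !grepl("(ss|us|is)$", w)) {
        tokens$features[i] <- "number=plural"
        tokens$lemma[i] <- sub("s$", "", w)
      }
    }
    i <- i + 1L
  }
  tokens
}

has_feature <- function(features, key, value) {
  grepl(paste0("(^|;)", key, "=", value, "($|;)"), features)
}

#' Disambiguate part-of-speech
#'
#' Tokens whose lexicon lookup yields several categories are resolved by an
#' injected tagger callback; the default callback applies deterministic
#' context rules: `to` before a base verb is an infinitive marker
#' (complementizer), BE/HAVE/DO forms are auxiliaries before a participle or
#' base verb and main verbs otherwise, a noun/verb-ambiguous token is a noun
#' after a determiner/adjective/preposition and a verb after a noun,
#' pronoun, or auxiliary (scanning over adverbs), and a participle directly
#' after a determiner, adjective, or hyphen is demoted to adjective.
#'
#' @param tokens looked-up tokens from [lexicon_lookup()].
#' @param tagger optional callback `function(tokens, i, candidates)`
#'   returning one category; it must return a member of `candidates`.
#' @return tokens with a single `pos` column.
#' @export
disambiguate_pos <- function(tokens, tagger = NULL) {
  n <- nrow(tokens)
  tokens$pos <- NA_character_
  if (!n) return(tokens)
  for (i in seq_len(n)) {
    cands <- strsplit(tokens$cats[i], ";", fixed = TRUE)[[1]]
    if (length(cands) == 1L) { tokens$pos[i] <- cands; next }
    if (!is.null(tagger)) {
      choice <- tagger(tokens, i, cands)
      if (!choice %in% cands) {
        stop("tagger callback returned a category not among the candidates: ",
             choice, call. = FALSE)
      }
      tokens$pos[i] <- choice
      next
    }
    tokens$pos[i] <- default_tag(tokens, i, cands)
  }
  # contextual demotions
  for (i in seq_len(n)) {
    if (tokens$pos[i] %in% c("verb") &&
        (has_feature(tokens$features[i], "tense", "pastpart") ||
         has_feature(tokens$features[i], "tense", "prespart"))) {
      prev <- if (i > 1L) i - 1L else NA_integer_
      if (!is.na(prev) &&
          (tokens$text[prev] == "-" ||
           tokens$pos[prev] %in% c("det", "adj", "num"))) {
        tokens$pos[i] <- "adj"
      }
    }
  }
  tokens
}

default_tag <- function(tokens, i, cands) {
  nxt <- next_non_adv(tokens, i)
  prev <- prev_non_adv(tokens, i)
  if ("compl" %in% cands && tokens$lemma[i] == "that") return("compl")
  if (all(sort(cands) == c("compl", "det")) ) return("det")
  if ("prep" %in% cands && "compl" %in% cands) return("prep")
  if ("aux" %in% cands) {
    if (!is.na(nxt) && grepl("verb", tokens$cats[nxt]) &&
        (has_feature(tokens$features[nxt], "tense", "pastpart") ||
         has_feature(tokens$features[nxt], "tense", "prespart") ||
         tokens$lemma[nxt] == tolower(tokens$text[nxt]))) {
      return("aux")
    }
    return(setdiff(cands, "aux")[1] %||% "aux")
  }
  if ("noun" %in% cands && "verb" %in% cands) {
    if (is.na(prev)) return("noun")
    pp <- tokens$pos[prev]
    if (is.na(pp)) pp <- strsplit(tokens$cats[prev], ";", fixed = TRUE)[[1]][1]
    if (pp %in% c("det", "adj", "num", "prep")) return("noun")
    if (pp %in% c("noun", "pron", "aux", "modal", "compl")) return("verb")
    return("noun")
  }
  if ("prep" %in% cands) return("prep")
  cands[1]
}

next_non_adv <- function(tokens, i) {
  j <- i + 1L
  while (j <= nrow(tokens) && (grepl("(^|;)adv($|;)", tokens$cats[j]) ||
                               tokens$text[j] %in% c("-"))) j <- j + 1L
  if (j <= nrow(tokens)) j else NA_integer_
}

prev_non_adv <- function(tokens, i) {
  j <- i - 1L
  while (j >= 1L && grepl("(^|;)adv($|;)", tokens$cats[j])) j <- j - 1L
  if (j >= 1L) j else NA_integer_
}

# special handling for "to": infinitive marker before a base verb
resolve_to <- function(tokens) {
  for (i in seq_len(nrow(tokens))) {
    if (tokens$lemma[i] == "to" && tokens$pos[i] == "prep") {
      j <- i + 1L
      if (j <= nrow(tokens) && grepl("verb", tokens$cats[j]) &&
          tolower(tokens$text[j]) == tokens$lemma[j]) {
        tokens$pos[i] <- "compl"
      }
    }
  }
  tokens
}

# mark multi-word conjunctions and appositive markers ("such as") so the
# chunker treats them as single units
mark_multiword_markers <- function(tokens) {
  tokens$marker <- NA_character_
  lower <- tolower(tokens$text)
  mark <- function(tokens, seqs, label) {
    for (s in seqs) {
      k <- length(s)
      for (i in seq_len(max(0L, nrow(tokens) - k + 1L))) {
        if (all(lower[i:(i + k - 1L)] == s)) {
          tokens$pos[i:(i + k - 1L)] <- label
          tokens$marker[i:(i + k - 1L)] <- paste(s, collapse = " ")
        }
      }
    }
    tokens
  }
  tokens <- mark(tokens, MULTIWORD_CONJUNCTIONS, "conj")
  mark(tokens, APPOSITIVE_MARKERS, "appos")
}

#' Chunk a disambiguated sentence into phrases
#'
#' @param tokens data.frame from [disambiguate_pos()].
#' @return list of phrases; each phrase is a list with `kind` (`NP`, `PP`,
#'   `VERB`, `CONJ`, `COMPL`, `APPOS`, `ADJ`, `PUNCT`, `OTHER`), `first`,
#'   `last` (token indices), `prep` (token index, PP only), `head`,
#'   `sem_head`, `mods` (token indices), and an empty `mappings` list.
#' @export
chunk_phrases <- function(tokens) {
  tokens <- resolve_to(tokens)
  tokens <- mark_multiword_markers(tokens)
  phrases <- list()
  cur <- integer()
  cur_prep <- NA_integer_
  flush <- function() {
    if (length(cur)) {
      phrases[[length(phrases) + 1L]] <<- finish_phrase(tokens, cur, cur_prep)
    }
    cur <<- integer(); cur_prep <<- NA_integer_
  }
  emit <- function(kind, idx) {
    phrases[[length(phrases) + 1L]] <<- list(
      kind = kind, first = idx[1], last = idx[length(idx)],
      prep = NA_integer_, head = NA_integer_, sem_head = NA_integer_,
      mods = integer(), mappings = list())
  }
  i <- 1L
  n <- nrow(tokens)
  while (i <= n) {
    pos <- tokens$pos[i]
    if (!is.na(tokens$marker[i])) {
      span <- i
      while (span[length(span)] < n &&
             !is.na(tokens$marker[span[length(span)] + 1L]) &&
             tokens$marker[span[length(span)] + 1L] == tokens$marker[i]) {
        span <- c(span, span[length(span)] + 1L)
      }
      flush(); emit(if (pos == "appos") "APPOS" else "CONJ", span)
      i <- span[length(span)] + 1L
      next
    }
    if (pos %in% c("verb", "aux", "modal")) {
      flush(); emit("VERB", i); i <- i + 1L; next
    }
    if (pos == "conj") { flush(); emit("CONJ", i); i <- i + 1L; next }
    if (pos == "compl") { flush(); emit("COMPL", i); i <- i + 1L; next }
    if (pos == "prep") { flush(); cur <- i; cur_prep <- i; i <- i + 1L; next }
    if (pos == "punct") {
      if (tokens$text[i] == "-" && length(cur)) {
        # hyphen joins its neighbours inside a phrase
        cur <- c(cur, i); i <- i + 1L; next
      }
      flush(); emit("PUNCT", i); i <- i + 1L; next
    }
    if (!length(cur)) cur <- i else cur <- c(cur, i)
    i <- i + 1L
  }
  flush()
  phrases
}

finish_phrase <- function(tokens, idx, prep) {
  pos <- tokens$pos[idx]
  nouns <- idx[pos %in% c("noun", "pron")]
  kind <- if (!is.na(prep)) {
    if (length(nouns)) "PP" else "OTHER"
  } else if (length(nouns)) "NP"
  else if (any(pos == "adj")) "ADJ"
  else "OTHER"
  head <- if (length(nouns)) nouns[length(nouns)] else NA_integer_
  mods <- setdiff(idx[pos %in% c("noun", "adj")], head)
  list(kind = kind, first = idx[1], last = idx[length(idx)],
       prep = prep, head = head, sem_head = head, mods = mods,
       mappings = list())
}

phrase_text <- function(sentence, tokens, phrase) {
  span_text(sentence, tokens, phrase$first, phrase$last)
}
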