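# Pre-linguistic analysis: MEDLINE parsing, sentence splitting, tokenization,
# and acronym/abbreviation detection. All offsets are 0-based, half-open;
# output serializers convert where a rendering requires otherwise.

#' Parse MEDLINE-format or plain text into documents
#'
#' MEDLINE field format: `PMID- `, `TI  - `, `AB  - ` fields with
#' continuation lines (leading whitespace) joined by single spaces; records
#' separated by their `PMID-` lines (or blank lines). Input without any
#' MEDLINE field is treated as a single plain-text document with an empty
#' pmid and title.
#'
#' @param text character scalar (or vector of lines).
#' @return list of documents, each a list with `pmid`, `title`, `abstract`,
#'   and `raw_text` (`title` and `abstract` joined; equal to the text itself
#'   for plain input).
#' @export
parse_medline <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (!length(lines) || !any(nzchar(trimws(lines)))) return(list())
  is_field <- grepl("^[A-Z][A-Z0-9]{1,3} *- ", lines)
  if (!any(is_field)) {
    body <- paste(lines, collapse = "\n")
    return(list(new_document(pmid = "", title = "", abstract = body)))
  }
  # split into records at PMID fields (fall back: blank-line separation)
  starts <- grep("^PMID *- ", lines)
  if (!length(starts)) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  docs <- list()
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    fields <- list()
    cur <- NULL
    for (i in seq_along(rec)) {
      ln <- rec[i]
      m <- regmatches(ln, regexec("^([A-Z][A-Z0-9]{1,3}) *- (.*)$", ln))[[1]]
      if (length(m) == 3) {
        cur <- m[2]
        fields[[cur]] <- c(fields[[cur]], m[3])
      } else if (grepl("^\\s+\\S", ln)) {
        if (is.null(cur)) {
          stop(sprintf("unparseable MEDLINE field structure at line %d: %s",
                       starts[k] + i - 1L, ln), call. = FALSE)
        }
        n <- length(fields[[cur]])
        fields[[cur]][n] <- paste(fields[[cur]][n], trimws(ln))
      } else if (nzchar(trimws(ln))) {
        stop(sprintf("unparseable MEDLINE field structure at line %d: %s",
                     starts[k] + i - 1L, ln), call. = FALSE)
      }
    }
    docs[[k]] <- new_document(
      pmid = trimws(paste(fields[["PMID"]] %||% "", collapse = " ")),
      title = paste(fields[["TI"]] %||% "", collapse = " "),
      abstract = paste(fields[["AB"]] %||% "", collapse = " "))
  }
  docs
}

new_document <- function(pmid, title, abstract) {
  raw <- if (nzchar(title)) paste0(title, "\n", abstract) else abstract
  structure(list(pmid = pmid, title = title, abstract = abstract,
                 raw_text = raw), class = "mp_document")
}

# Word tokens before a period that do not end a sentence.
SPLIT_ABBREVIATIONS <- c("approx", "vs", "e.g", "i.e", "etc", "dr", "fig",
                         "figs", "al", "no", "st", "ca", "cf", "resp")

#' Split a document into sentences
#'
#' Rule-based splitting on `.`, `?`, `!` followed by whitespace and an
#' upper-case letter or digit, with an abbreviation exception list
#' ("approx.", "e.g.", "et al.", ...). Title text (when present) is emitted
#' first with section `TITLE`.
#'
#' @param document a document from [parse_medline()], or a character scalar
#'   (treated as plain abstract text).
#' @return data.frame with columns `text`, `start`, `end` (0-based,
#'   half-open offsets into the document's `raw_text`), `section`.
#' @export
split_sentences <- function(document) {
  if (is.character(document)) document <- new_document("", "", document)
  raw <- document$raw_text
  out <- data.frame(text = character(), start = integer(), end = integer(),
                    section = character(), stringsAsFactors = FALSE)
  if (!nzchar(raw)) return(out)
  segments <- if (nzchar(document$title)) {
    list(list(start = 0L, text = document$title, section = "TITLE"),
         list(start = nchar(document$title) + 1L, text = document$abstract,
              section = "ABSTRACT"))
  } else {
    list(list(start = 0L, text = document$abstract, section = "ABSTRACT"))
  }
  for (seg in segments) {
    if (!nzchar(seg$text)) next
    bounds <- sentence_breaks(seg$text)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, nchar(seg$text))
    for (i in seq_along(starts)) {
      s <- starts[i]; e <- ends[i]
      txt <- substr(seg$text, s, e)
      lead <- nchar(txt) - nchar(sub("^\\s+", "", txt))
      trail <- nchar(txt) - nchar(sub("\\s+$", "", txt))
      s <- s + lead; e <- e - trail
      if (e < s) next
      out <- rbind(out, data.frame(
        text = substr(seg$text, s, e),
        start = seg$start + s - 1L, end = seg$start + e,
        section = seg$section, stringsAsFactors = FALSE))
    }
  }
  stopifnot(all(substring(raw, out$start + 1L, out$end) == out$text))
  out
}

# 1-based positions (within text) after which a sentence break occurs
sentence_breaks <- function(text) {
  hits <- gregexpr("[.?!]", text)[[1]]
  if (hits[1] == -1) return(integer())
  keep <- integer()
  for (pos in as.integer(hits)) {
    rest <- substr(text, pos + 1L, nchar(text))
    if (!grepl("^\\s+[A-Z0-9(\"]", rest)) next
    if (substr(text, pos, pos) == ".") {
      before <- substr(text, max(1L, pos - 20L), pos - 1L)
      word <- tolower(sub(".*?([A-Za-z][A-Za-z.]*)$", "\\1", before))
      if (word %in% SPLIT_ABBREVIATIONS) next
      if (grepl("(^|\\s)et$", tolower(before)) || word == "al") next
    }
    keep <- c(keep, pos)
  }
  keep
}

#' Tokenize a sentence
#'
#' Hyphens, parentheses, commas, and other punctuation (including the
#' sentence-final period) are single-character tokens; runs of
#' letters/digits (with internal apostrophes) form word tokens. Offsets are
#' 0-based half-open within the sentence, so concatenating tokens with their
#' original gaps reconstructs the sentence.
#'
#' @param sentence character scalar.
#' @return data.frame with columns `text`, `start`, `end`, `is_punct`.
#' @export
tokenize <- function(sentence) {
  m <- gregexpr("[A-Za-z0-9]+(?:'[A-Za-z]+)?|[^A-Za-z0-9[:space:]]", sentence)[[1]]
  if (m[1] == -1) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      is_punct = logical(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  txt <- substring(sentence, starts, starts + lens - 1L)
  out <- data.frame(text = txt, start = starts - 1L, end = starts + lens - 1L,
                    is_punct = !grepl("[A-Za-z0-9]", txt), stringsAsFactors = FALSE)
  stopifnot(all(substring(sentence, out$start + 1L, out$end) == out$text))
  out
}

# reconstruct the source substring covered by tokens i..j
span_text <- function(sentence, tokens, i, j) {
  substring(sentence, tokens$start[i] + 1L, tokens$end[j])
}

#' Detect abbreviation definitions (Schwartz-Hearst)
#'
#' Matches a bracketed short form against a candidate long form preceding it
#' in the same sentence, using the Schwartz-Hearst character-matching
#' procedure: scanning the short form right to left, every alphanumeric
#' character must appear in the long form (in order), and its first
#' character must match at the start of a long-form word. The long-form
#' window is bounded by min(|sf| + 5, |sf| * 2) words. Detected short forms
#' inherit the long form's concept mappings downstream.
#'
#' @param sentence sentence text.
#' @param tokens tokenization of the sentence (from [tokenize()]); computed
#'   when missing.
#' @return data.frame with columns `short`, `long`, `sf_start_tok`,
#'   `sf_end_tok`, `lf_start_tok`, `lf_end_tok` (token indices, inclusive).
#' @export
detect_abbreviations <- function(sentence, tokens = tokenize(sentence)) {
  out <- data.frame(short = character(), long = character(),
                    sf_start_tok = integer(), sf_end_tok = integer(),
                    lf_start_tok = integer(), lf_end_tok = integer(),
                    stringsAsFactors = FALSE)
  opens <- which(tokens$text == "(")
  for (o in opens) {
    close <- which(tokens$text == ")" & seq_len(nrow(tokens)) > o)
    if (!length(close)) next
    close <- close[1]
    inner <- (o + 1L):(close - 1L)
    inner <- inner[inner <= nrow(tokens) & inner >= o + 1L]
    if (!length(inner) || length(inner) > 3L) next
    sf <- span_text(sentence, tokens, inner[1], inner[length(inner)])
    if (!valid_short_form(sf)) next
    nwords <- length(strsplit(sf, "\\s+")[[1]])
    max_words <- min(nchar(gsub("[^A-Za-z0-9]", "", sf)) + 5L,
                     nchar(gsub("[^A-Za-z0-9]", "", sf)) * 2L)
    word_idx <- which(!tokens$is_punct & seq_len(nrow(tokens)) < o)
    if (!length(word_idx)) next
    cand_first <- word_idx[max(1L, length(word_idx) - max_words + 1L)]
    lf_hit <- NULL
    # try progressively longer windows ending just before '('; keep shortest
    # long form that satisfies the character-matching certificate
    last_word <- word_idx[length(word_idx)]
    for (first in rev(word_idx[word_idx >= cand_first])) {
      lf <- span_text(sentence, tokens, first, last_word)
      if (sh_matches(sf, lf)) { lf_hit <- c(first, last_word); break }
    }
    if (is.null(lf_hit)) next
    lf <- span_text(sentence, tokens, lf_hit[1], lf_hit[2])
    if (nchar(sf) >= nchar(lf)) next
    out <- rbind(out, data.frame(
      short = sf, long = lf, sf_start_tok = inner[1], sf_end_tok = inner[length(inner)],
      lf_start_tok = lf_hit[1], lf_end_tok = lf_hit[2], stringsAsFactors = FALSE))
  }
  out
}

valid_short_form <- function(sf) {
  chars <- nchar(sf)
  chars >= 2 && chars <= 10 &&
    grepl("^[A-Za-z0-9]", sf) && grepl("[A-Za-z]", sf) &&
    length(strsplit(sf, "\\s+")[[1]]) <= 2
}

# Schwartz-Hearst right-to-left character matching
sh_matches <- function(sf, lf) {
  s <- tolower(strsplit(sf, "")[[1]])
  s <- s[grepl("[a-z0-9]", s)]
  l <- tolower(strsplit(lf, "")[[1]])
  si <- length(s); li <- length(l)
  while (si > 0) {
    ch <- s[si]
    while (li > 0 && (l[li] != ch ||
                      (si == 1 && li > 1 && grepl("[a-z0-9]", l[li - 1])))) {
      li <- li - 1
    }
    if (li == 0) return(FALSE)
    li <- li - 1
    si <- si - 1
  }
  TRUE
}
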