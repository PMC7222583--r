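# The extraction pipeline: pre-linguistic analysis, lexical/syntactic
# analysis, referential analysis, post-referential analysis, and relational
# analysis, orchestrated per document. Domain processing and sortal anaphora
# resolution are optional stages.

#' Pipeline run options
#'
#' @param input_format `"plain"` or `"medline"`.
#' @param anaphora enable sortal anaphora resolution (off by default).
#' @param generic_extension enable the extended concept set (`-N`).
#' @param generic_modification enable generic recontextualizations (`-n`).
#' @param domain optional name of a registered domain extension
#'   (e.g. `"disaster"`).
#' @param tagger optional part-of-speech tagger callback
#'   (see [disambiguate_pos()]).
#' @param disambiguator optional same-span concept disambiguation hook
#'   (see [map_concepts()]).
#' @return a `run_options` list.
#' @export
run_options <- function(input_format = c("plain", "medline"),
                        anaphora = FALSE, generic_extension = FALSE,
                        generic_modification = FALSE, domain = NULL,
                        tagger = NULL, disambiguator = NULL) {
  structure(list(input_format = match.arg(input_format), anaphora = anaphora,
                 generic_extension = generic_extension,
                 generic_modification = generic_modification, domain = domain,
                 tagger = tagger, disambiguator = disambiguator),
            class = "run_options")
}

apply_run_extensions <- function(kb, options) {
  if (isTRUE(options$generic_extension) &&
      !is.null(kb$extensions$generic_concepts)) {
    kb <- apply_domain_extension(kb, kb$extensions$generic_concepts)
  }
  if (isTRUE(options$generic_modification) &&
      !is.null(kb$extensions$generic_recontextualization)) {
    kb <- apply_domain_extension(kb, kb$extensions$generic_recontextualization)
  }
  if (!is.null(options$domain)) {
    ext <- kb$extensions[[options$domain]]
    if (is.null(ext)) {
      stop("no registered domain extension named '", options$domain, "'",
           call. = FALSE)
    }
    kb <- apply_domain_extension(kb, ext)
  }
  kb
}

#' Annotate one sentence
#'
#' Runs tokenization, abbreviation detection, lexicon lookup, POS
#' disambiguation, chunking, concept and gene mapping (with abbreviation
#' inheritance), negated-mention detection, empty-head marking, and
#' coordination detection.
#'
#' @param text sentence text.
#' @param kb a `predication_kb`.
#' @param options a [run_options()] list.
#' @param index sentence index within the document.
#' @param offset character offset of the sentence within the document.
#' @param section `TITLE`/`ABSTRACT`/`BODY`.
#' @param abbrev_env optional environment carrying the document-level
#'   abbreviation registry (short form -> concept ids).
#' @return an annotated sentence (list with `text`, `tokens`, `phrases`,
#'   `coordinations`, `abbreviations`, `index`, `offset`, `section`).
#' @export
annotate_sentence <- function(text, kb, options = run_options(), index = 1L,
                              offset = 0L, section = "ABSTRACT",
                              abbrev_env = NULL) {
  tokens <- tokenize(text)
  tokens <- lexicon_lookup(tokens, kb)
  tokens <- disambiguate_pos(tokens, tagger = options$tagger)
  abbrevs <- detect_abbreviations(text, tokens)
  phrases <- chunk_phrases(tokens)
  extra_index <- if (!is.null(abbrev_env)) as.list(abbrev_env) else NULL
  for (p in seq_along(phrases)) {
    maps <- c(map_concepts(phrases[[p]], tokens, text, kb,
                           extra_index = extra_index,
                           disambiguator = options$disambiguator),
              map_genes(phrases[[p]], tokens, text, kb))
    phrases[[p]]$mappings <- order_mappings(maps)
  }
  # abbreviation inheritance: the short form inherits the long form's
  # mappings, within the sentence and (via the registry) downstream
  if (nrow(abbrevs)) {
    for (k in seq_len(nrow(abbrevs))) {
      ab <- abbrevs[k, ]
      lf_maps <- list()
      for (p in seq_along(phrases)) {
        lf_maps <- c(lf_maps, Filter(function(m)
          m$start_tok >= ab$lf_start_tok && m$end_tok <= ab$lf_end_tok,
          phrases[[p]]$mappings))
      }
      if (!length(lf_maps)) next
      sf_key <- normalize_surface(ab$short)
      if (!is.null(abbrev_env)) {
        abbrev_env[[sf_key]] <- unique(c(abbrev_env[[sf_key]],
          vapply(lf_maps, `[[`, "", "concept_id")))
      }
      for (p in seq_along(phrases)) {
        ph <- phrases[[p]]
        if (ph$first <= ab$sf_start_tok && ph$last >= ab$sf_end_tok) {
          inh <- lapply(lf_maps, function(m) {
            m$start_tok <- ab$sf_start_tok; m$end_tok <- ab$sf_end_tok
            m$start <- tokens$start[ab$sf_start_tok]
            m$end <- tokens$end[ab$sf_end_tok]
            m$covers_head <- !is.na(ph$head) && ph$head >= ab$sf_start_tok &&
              ph$head <= ab$sf_end_tok
            m$synonym <- ab$short
            m
          })
          keys <- vapply(phrases[[p]]$mappings, function(m)
            paste(m$concept_id, m$start_tok), "")
          inh <- Filter(function(m) !paste(m$concept_id, m$start_tok) %in% keys, inh)
          phrases[[p]]$mappings <- order_mappings(c(phrases[[p]]$mappings, inh))
        }
      }
    }
  }
  phrases <- detect_negated_mentions(phrases, tokens, kb$word_lists)
  for (p in seq_along(phrases)) {
    phrases[[p]] <- mark_empty_heads(phrases[[p]], tokens, kb$word_lists)
  }
  sent <- list(text = text, tokens = tokens, phrases = phrases,
               abbreviations = abbrevs, index = index, offset = offset,
               section = section)
  sent$coordinations <- detect_coordination(phrases, tokens, kb)
  class(sent) <- "mp_sentence"
  sent
}

#' Run the full extraction pipeline on one document
#'
#' Executes the five analysis phases in order and returns per-sentence
#' entity mappings plus the document's predications. Optional stages (domain
#' processing, sortal anaphora resolution) are gated by the options.
#'
#' @param document a document from [parse_medline()] or a character scalar
#'   of plain text.
#' @param kb a `predication_kb`.
#' @param options a [run_options()] list.
#' @return an object of class `mp_result`: list with `document`,
#'   `sentences` (annotated), `predications` (list), `anaphor_links`,
#'   `stage_log` (per-stage counts).
#' @export
run_pipeline <- function(document, kb, options = run_options()) {
  if (is.character(document)) document <- new_document("", "", document)
  kb <- apply_run_extensions(kb, options)
  sents <- split_sentences(document)
  abbrev_env <- new.env(parent = emptyenv())
  annotated <- list()
  for (i in seq_len(nrow(sents))) {
    annotated[[i]] <- annotate_sentence(
      sents$text[i], kb, options, index = i, offset = sents$start[i],
      section = sents$section[i], abbrev_env = abbrev_env)
  }
  links <- if (isTRUE(options$anaphora)) {
    resolve_sortal_anaphora(annotated, kb)
  } else list()
  preds <- list()
  for (sent in annotated) {
    ctx <- new_arg_context(sent)
    hyper <- resolve_hypernymy(sent, kb)
    for (h in hyper) {
      ctx$preds[[length(ctx$preds) + 1L]] <- h
    }
    for (cp in process_comparatives(sent, kb, ctx)) {
      ctx$preds[[length(ctx$preds) + 1L]] <- cp
    }
    instances <- detect_triggers(sent, kb)
    for (inst in instances) identify_arguments(inst, sent, kb, ctx)
    sent_preds <- negate_predications(ctx$preds, sent, kb)
    preds <- c(preds, sent_preds)
  }
  preds <- substitute_anaphora(preds, links, annotated, kb)
  preds <- infer_predications(preds, kb)
  # deduplicate while preserving order
  keys <- vapply(preds, predication_key, "")
  preds <- preds[!duplicated(keys)]
  log <- list(
    sentences = length(annotated),
    phrases = sum(vapply(annotated, function(s) length(s$phrases), 0L)),
    mappings = sum(vapply(annotated, function(s)
      sum(lengths(lapply(s$phrases, `[[`, "mappings"))), 0L)),
    coordinations = sum(vapply(annotated, function(s)
      length(s$coordinations), 0L)),
    anaphor_links = length(links),
    predications = length(preds))
  structure(list(document = document, sentences = annotated,
                 predications = preds, anaphor_links = links,
                 stage_log = log),
            class = "mp_result")
}

#' Extract predications from text
#'
#' Top-level convenience wrapper: parses the input (plain or MEDLINE),
#' runs the pipeline per document, and returns the results.
#'
#' @param text character scalar of input text.
#' @param kb a `predication_kb` (defaults to the bundled fixture bundle).
#' @param options a [run_options()] list; `...` is passed to [run_options()]
#'   when `options` is NULL.
#' @param ... arguments for [run_options()].
#' @return a list of `mp_result` objects (one per document).
#' @export
extract_predications <- function(text, kb = fixture_kb(), options = NULL, ...) {
  if (is.null(options)) options <- run_options(...)
  docs <- if (options$input_format == "medline") {
    parse_medline(text)
  } else {
    list(new_document("", "", text))
  }
  lapply(docs, run_pipeline, kb = kb, options = options)
}

#' Predications of a result as a data.frame
#'
#' @param result an `mp_result` (or list of them).
#' @return data.frame with one row per predication: subject id/name/type,
#'   predicate (NEG_-prefixed when negated), object id/name/type, flags,
#'   indicator information, and sentence ids.
#' @export
predications <- function(result) {
  results <- if (inherits(result, "mp_result")) list(result) else result
  rows <- list()
  for (res in results) {
    for (p in res$predications) {
      rows[[length(rows) + 1L]] <- data.frame(
        pmid = res$document$pmid %||% "",
        subj_id = p$subj$concept_id, subj_name = p$subj$name,
        subj_type = p$subj$semtypes[1],
        predicate = if (p$negated) paste0("NEG_", p$predicate) else p$predicate,
        obj_id = p$obj$concept_id, obj_name = p$obj$name,
        obj_type = p$obj$semtypes[1],
        negated = p$negated, inferred = p$inferred,
        indicator_type = p$indicator_type %||% NA_character_,
        indicator_text = p$indicator_text %||% NA_character_,
        scale = p$scale %||% NA_character_,
        sentence = p$sentence, sentence2 = p$sentence2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pmid = character(), subj_id = character(),
                      subj_name = character(), subj_type = character(),
                      predicate = character(), obj_id = character(),
                      obj_name = character(), obj_type = character(),
                      negated = logical(), inferred = logical(),
                      indicator_type = character(), indicator_text = character(),
                      scale = character(), sentence = integer(),
                      sentence2 = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.mp_result <- function(x, ...) {
  cat("<mp_result> ", x$stage_log$sentences, " sentence(s), ",
      x$stage_log$predications, " predication(s)\n", sep = "")
  cat(write_simplified(x), sep = "\n")
  invisible(x)
}
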