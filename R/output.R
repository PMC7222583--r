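# Output serializations. Three formats carry the same predication multiset:
# the simplified plain-text format, a pipe-delimited full-fielded format
# (dialect documented below), and an XML rendering of the full-fielded
# content.
#
# Full-fielded dialect (pipe-delimited, one record per line):
#   SE|pmid|sentence_idx|section|start|end|text
#   EN|pmid|sentence_idx|concept_id|name|semtypes(,)|start|end|score|negated
#   PR|pmid|sentence_ids(,)|subj_id|subj_name|predicate|obj_id|obj_name|
#      indicator_type|indicator_text|negated|inferred|scale
#   CO|pmid|anaphor_sentence|anaphor_text|kind|antecedent_ids(,)
# Offsets are 0-based half-open, document-relative.

render_argument <- function(m) {
  sprintf("%s: %s (%s)", m$concept_id, m$name, m$semtypes[1])
}

render_predicate <- function(p) {
  tolower(if (p$negated) paste0("NEG_", p$predicate) else p$predicate)
}

#' Simplified plain-text output
#'
#' Each sentence line is followed by one line per predication:
#' `CUI: Name (SemType)- predicate -CUI: Name (SemType)`; negated
#' predicates render with a `neg_` prefix, inferred ones with an `(infer)`
#' annotation.
#'
#' @param result an `mp_result` (or list of them).
#' @return character vector of output lines.
#' @export
write_simplified <- function(result) {
  results <- if (inherits(result, "mp_result")) list(result) else result
  out <- character()
  for (res in results) {
    for (s in seq_along(res$sentences)) {
      sent <- res$sentences[[s]]
      out <- c(out, sent$text)
      for (p in res$predications) {
        if (p$sentence != s) next
        label <- render_predicate(p)
        if (p$inferred) label <- paste0(label, "(infer)")
        out <- c(out, sprintf("%s- %s -%s", render_argument(p$subj), label,
                              render_argument(p$obj)))
      }
    }
  }
  out
}

#' Full-fielded output
#'
#' Pipe-delimited records for sentences (`SE`), entities (`EN`, with
#' document offsets, match score, and negation flag), predications (`PR`,
#' with the indicator type -- verb/prep/noun/adj/mod_head/comparative/
#' hypernym/inference), and coreference links (`CO`).
#'
#' @param result an `mp_result` (or list of them).
#' @return character vector of output lines (header first).
#' @export
write_full_fielded <- function(result) {
  results <- if (inherits(result, "mp_result")) list(result) else result
  out <- "FORMAT|minipredicate-full-fielded-v1"
  for (res in results) {
    pmid <- res$document$pmid %||% ""
    for (s in seq_along(res$sentences)) {
      sent <- res$sentences[[s]]
      out <- c(out, paste("SE", pmid, s, sent$section, sent$offset,
                          sent$offset + nchar(sent$text), sent$text, sep = "|"))
      for (ph in sent$phrases) {
        for (m in ph$mappings) {
          out <- c(out, paste("EN", pmid, s, m$concept_id, m$name,
                              paste(m$semtypes, collapse = ","),
                              sent$offset + m$start, sent$offset + m$end,
                              m$score, tolower(m$negated), sep = "|"))
        }
      }
    }
    for (p in res$predications) {
      sids <- p$sentence
      if (!is.na(p$sentence2) && p$sentence2 != p$sentence) {
        sids <- c(p$sentence2, p$sentence)
      }
      blank_na <- function(x) if (is.null(x) || is.na(x)) "" else x
      out <- c(out, paste("PR", pmid, paste(sids, collapse = ","),
                          p$subj$concept_id, p$subj$name, render_predicate(p),
                          p$obj$concept_id, p$obj$name,
                          if (p$inferred) "inference" else blank_na(p$indicator_type),
                          blank_na(p$indicator_text), tolower(p$negated),
                          tolower(p$inferred), blank_na(p$scale), sep = "|"))
    }
    for (l in res$anaphor_links) {
      an <- res$sentences[[l$anaphor[1]]]
      ph <- an$phrases[[l$anaphor[2]]]
      ants <- vapply(l$antecedents, function(a) {
        m <- phrase_best_mapping(res$sentences[[a[1]]]$phrases[[a[2]]])
        if (is.null(m)) "" else m$concept_id
      }, "")
      out <- c(out, paste("CO", pmid, l$anaphor[1],
                          phrase_text(an$text, an$tokens, ph), l$kind,
                          paste(ants, collapse = ","), sep = "|"))
    }
  }
  out
}

#' XML output
#'
#' Well-formed XML mirroring the full-fielded content; invalid characters
#' are escaped by the serializer, never emitted raw.
#'
#' @param result an `mp_result` (or list of them).
#' @return character scalar of XML text.
#' @export
write_xml_output <- function(result) {
  results <- if (inherits(result, "mp_result")) list(result) else result
  root <- xml2::xml_new_root("predication_output", version = "1")
  for (res in results) {
    doc_node <- xml2::xml_add_child(root, "document",
                                    pmid = res$document$pmid %||% "")
    for (s in seq_along(res$sentences)) {
      sent <- res$sentences[[s]]
      snode <- xml2::xml_add_child(doc_node, "sentence", id = as.character(s),
                                   section = sent$section,
                                   start = as.character(sent$offset),
                                   end = as.character(sent$offset + nchar(sent$text)))
      xml2::xml_add_child(snode, "text", sent$text)
      for (ph in sent$phrases) {
        for (m in ph$mappings) {
          xml2::xml_add_child(snode, "entity", id = m$concept_id, name = m$name,
                              semtypes = paste(m$semtypes, collapse = ","),
                              start = as.character(sent$offset + m$start),
                              end = as.character(sent$offset + m$end),
                              score = as.character(m$score),
                              negated = tolower(m$negated))
        }
      }
    }
    for (p in res$predications) {
      pnode <- xml2::xml_add_child(doc_node, "predication",
                                   predicate = render_predicate(p),
                                   negated = tolower(p$negated),
                                   inferred = tolower(p$inferred),
                                   indicator_type = if (p$inferred) "inference"
                                                    else p$indicator_type %||% "",
                                   sentence = as.character(p$sentence))
      if (!is.na(p$sentence2)) {
        xml2::xml_set_attr(pnode, "sentence2", as.character(p$sentence2))
      }
      if (!is.na(p$scale %||% NA)) xml2::xml_set_attr(pnode, "scale", p$scale)
      xml2::xml_add_child(pnode, "subject", id = p$subj$concept_id,
                          name = p$subj$name, semtype = p$subj$semtypes[1])
      xml2::xml_add_child(pnode, "object", id = p$obj$concept_id,
                          name = p$obj$name, semtype = p$obj$semtypes[1])
    }
  }
  as.character(root)
}

#' Knowledge-base statistics
#'
#' Counts supporting resource validation: ontology triples by source,
#' distinct associative predicates, indicator rules by predicate and by
#' structural class (single-word, phrase/clausal, modifier-head).
#'
#' @param kb a `predication_kb`.
#' @return a list of counts.
#' @export
kb_stats <- function(kb) {
  rules <- kb$rules
  is_mod_head <- rules$pos == "MOD_HEAD"
  is_phrase <- !is_mod_head & grepl("[{ ]", rules$lexeme)
  list(
    ontology_total = nrow(kb$ontology),
    ontology_by_source = table(kb$ontology$source),
    predicates = sort(unique(base_predicate(kb$ontology$predicate))),
    n_predicates = length(unique(base_predicate(kb$ontology$predicate))),
    rules_total = nrow(rules),
    rules_single_word = sum(!is_mod_head & !is_phrase),
    rules_phrase = sum(is_phrase),
    rules_mod_head = sum(is_mod_head),
    rules_by_predicate = sort(table(base_predicate(rules$predicate)),
                              decreasing = TRUE),
    concepts = nrow(kb$concepts),
    synonyms = nrow(kb$synonyms),
    hierarchy_edges = nrow(kb$hierarchy),
    gene_aliases = nrow(kb$gene_index))
}
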