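# Readers and writers for the knowledge-base file dialects.
#
# Ontology file:        one `Subject Type-PREDICATE-Object Type` triple per
#                       line, literal hyphen delimiters, predicate upper-case.
# Indicator rule file:  one `lexeme:pos:cue ->PREDICATE` per line ("->" or the
#                       arrow character both accepted); cue is `none`,
#                       `word(subject)`, `word(object)`, or `between-and`.
# Concept dictionary:   surface <TAB> id <TAB> name <TAB> type[;type] <TAB> source
# Hierarchy:            child_id <TAB> parent_id
# Semantic groups:      type <TAB> group
# Word lists:           one entry per line
# Gene index:           alias <TAB> gene_id <TAB> symbol
# Lexicon:              surface <TAB> base <TAB> cat <TAB> features
# Inference rules:      IF <X-PRED-Y AND Z-PRED-Y> THEN <X-PRED-Z>
# Domain extension:     YAML with the four extension sections.
#
# All readers support a tolerant mode (default: skip blank lines and lines
# starting with '#', trim whitespace) and a strict mode (any unparseable
# line is an error).

read_resource_lines <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read resource file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- if (strict) seq_along(lines) else which(!grepl("^\\s*(#|$)", lines))
  list(lines = if (strict) lines[keep] else trimws(lines[keep]), numbers = keep)
}

resource_error <- function(path, numbers, bad, what) {
  stop(sprintf("%s in %s at line(s) %s", what, path,
               paste(numbers[bad], collapse = ", ")), call. = FALSE)
}

#' Read an ontology of licensed semantic-type triples
#'
#' @param path file of `Subject Type-PREDICATE-Object Type` lines.
#' @param source source tag attached to every triple (`SEMANTIC_NETWORK`,
#'   `SUPPLEMENTARY`, or `DOMAIN`).
#' @param strict fail on blank or comment lines too?
#' @param predicates allowed predicate inventory; labels outside it raise a
#'   validation error naming the label.
#' @return deduplicated data.frame with columns `subject_type`, `predicate`,
#'   `object_type`, `source`.
#' @export
read_ontology <- function(path, source = "SUPPLEMENTARY", strict = FALSE,
                          predicates = ASSOCIATIVE_PREDICATES) {
  res <- read_resource_lines(path, strict)
  if (!length(res$lines)) {
    return(data.frame(subject_type = character(), predicate = character(),
                      object_type = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(res$lines, regexec("^(.*[^-])-([A-Z][A-Z_]+)-([^-].*)$", res$lines))
  bad <- lengths(m) != 4
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed ontology line")
  out <- data.frame(
    subject_type = trimws(vapply(m, `[`, "", 2)),
    predicate = vapply(m, `[`, "", 3),
    object_type = trimws(vapply(m, `[`, "", 4)),
    source = source, stringsAsFactors = FALSE)
  if (!is.null(predicates)) {
    unknown <- setdiff(base_predicate(out$predicate), predicates)
    if (length(unknown)) {
      stop("unknown predicate label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  unique(out)
}

#' Read indicator rules
#'
#' Rules map a lexeme with a part-of-speech tag, and optionally an argument
#' cue, to a predicate: `treat:verb:none ->TREATS`,
#' `treatment:noun:with(subject) ->TREATS`. Multi-word lexemes and
#' alternation braces (`{increase,odds}`) are permitted; the reserved lexeme
#' `MOD_HEAD` marks structural rules over an NP's modifier-head pair.
#' An `!inverse` annotation after the predicate marks the rule
#' inverse-orientation-capable; predicates written with a `NEG_` prefix are
#' implicit negatives.
#'
#' @inheritParams read_ontology
#' @return data.frame with columns `lexeme`, `pos`, `cue_role`, `cue_word`,
#'   `predicate`, `inverse`, `implicit_negative`, `source`.
#' @export
read_indicator_rules <- function(path, source = "CORE", strict = FALSE) {
  res <- read_resource_lines(path, strict)
  empty <- data.frame(lexeme = character(), pos = character(),
                      cue_role = character(), cue_word = character(),
                      predicate = character(), inverse = logical(),
                      implicit_negative = logical(), source = character(),
                      stringsAsFactors = FALSE)
  if (!length(res$lines)) return(empty)
  pat <- "^(.+):(verb|noun|prep|adj|MOD_HEAD):([^ ]+)\\s*(->|\u2192)\\s*([A-Za-z_]+)( *!inverse)?$"
  m <- regmatches(res$lines, regexec(pat, res$lines))
  bad <- lengths(m) == 0
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed indicator rule")
  cue <- vapply(m, `[`, "", 4)
  cue_role <- rep(NA_character_, length(cue))
  cue_word <- rep(NA_character_, length(cue))
  is_cued <- cue != "none"
  cm <- regmatches(cue, regexec("^([A-Za-z-]+)\\((subject|object)\\)$", cue))
  ba <- cue == "between-and"
  cue_role[ba] <- "object"; cue_word[ba] <- "BETWEEN_AND"
  need <- is_cued & !ba
  badcue <- need & lengths(cm) != 3
  if (any(badcue)) resource_error(path, res$numbers, badcue, "unparseable cue specification")
  cue_word[need] <- vapply(cm[need], `[`, "", 2)
  cue_role[need] <- vapply(cm[need], `[`, "", 3)
  pred <- toupper(vapply(m, `[`, "", 6))
  lex <- vapply(m, `[`, "", 2)
  pos <- vapply(m, `[`, "", 3)
  structural <- pos == "MOD_HEAD"
  if (any(structural & is_cued)) {
    resource_error(path, res$numbers, structural & is_cued,
                   "structural (MOD_HEAD) rule may not carry a cue")
  }
  out <- data.frame(
    lexeme = ifelse(structural, "MOD_HEAD", tolower(lex)), pos = pos,
    cue_role = cue_role, cue_word = cue_word, predicate = pred,
    inverse = !is.na(vapply(m, `[`, "", 7)) & nzchar(vapply(m, `[`, "", 7)),
    implicit_negative = grepl("^NEG_", pred),
    source = source, stringsAsFactors = FALSE)
  unknown <- setdiff(base_predicate(out$predicate), ALL_PREDICATES)
  if (length(unknown) && source == "CORE") {
    stop("unknown predicate label(s) in rule file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unique(out)
}

#' Read a concept dictionary
#'
#' Delimited text, one synonym per row:
#' `surface <TAB> concept_id <TAB> preferred_name <TAB> type[;type] <TAB> source`.
#'
#' @inheritParams read_ontology
#' @return list with data.frames `concepts` (unique by id) and `synonyms`.
#' @export
read_concept_dictionary <- function(path, strict = FALSE) {
  res <- read_resource_lines(path, strict)
  if (!length(res$lines)) {
    return(list(concepts = data.frame(id = character(), name = character(),
                                      semtypes = character(), source = character(),
                                      stringsAsFactors = FALSE),
                synonyms = data.frame(surface = character(), id = character(),
                                      stringsAsFactors = FALSE)))
  }
  parts <- strsplit(res$lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed dictionary row")
  df <- data.frame(
    surface = vapply(parts, `[`, "", 1), id = vapply(parts, `[`, "", 2),
    name = vapply(parts, `[`, "", 3), semtypes = vapply(parts, `[`, "", 4),
    source = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE)
  concepts <- unique(df[c("id", "name", "semtypes", "source")])
  list(concepts = concepts, synonyms = df[c("surface", "id")])
}

#' Read two-column tab-separated resources
#'
#' `read_hierarchy()` reads `child_id <TAB> parent_id` edges;
#' `read_semantic_groups()` reads `semantic_type <TAB> group` rows.
#'
#' @inheritParams read_ontology
#' @return data.frame.
#' @export
read_hierarchy <- function(path, strict = FALSE) {
  read_two_col(path, c("child", "parent"), strict)
}

#' @rdname read_hierarchy
#' @export
read_semantic_groups <- function(path, strict = FALSE) {
  read_two_col(path, c("type", "group"), strict)
}

read_two_col <- function(path, cols, strict = FALSE) {
  res <- read_resource_lines(path, strict)
  out <- stats::setNames(data.frame(character(), character(), stringsAsFactors = FALSE), cols)
  if (!length(res$lines)) return(out)
  parts <- strsplit(res$lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed row")
  out <- stats::setNames(data.frame(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
                                    stringsAsFactors = FALSE), cols)
  unique(out)
}

#' Read a word list (one lower-cased entry per line)
#' @inheritParams read_ontology
#' @return character vector, duplicate-free.
#' @export
read_word_list <- function(path, strict = FALSE) {
  unique(tolower(read_resource_lines(path, strict)$lines))
}

#' Read a gene alias index
#'
#' Exact-match, case-normalized alias lookup: `alias <TAB> gene_id <TAB>
#' official_symbol`. One alias may map to several genes; all are kept.
#'
#' @inheritParams read_ontology
#' @return data.frame with columns `alias`, `gene_id`, `symbol`.
#' @export
read_gene_index <- function(path, strict = FALSE) {
  res <- read_resource_lines(path, strict)
  if (!length(res$lines)) {
    return(data.frame(alias = character(), gene_id = character(),
                      symbol = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(res$lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed gene index row")
  unique(data.frame(alias = vapply(parts, `[`, "", 1),
                    gene_id = vapply(parts, `[`, "", 2),
                    symbol = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE))
}

empty_lexicon <- function() {
  data.frame(surface = character(), base = character(), cat = character(),
             features = character(), stringsAsFactors = FALSE)
}

#' Read a lexicon
#'
#' `surface <TAB> base <TAB> cat <TAB> features` rows, one per (surface form,
#' homonymous record). `cat` is one of noun, verb, adj, adv, prep, aux,
#' modal, conj, compl, det, pron. `features` is a `;`-joined set of
#' `key=value` pairs: `number=plural`, `tense=pastpart`,
#' `subcat=to|from` (subcategorized prepositions), `nominalization=...`.
#' Multi-word surfaces ("calcium antagonists") are permitted.
#'
#' @inheritParams read_ontology
#' @return data.frame with columns `surface`, `base`, `cat`, `features`.
#' @export
read_lexicon <- function(path, strict = FALSE) {
  res <- read_resource_lines(path, strict)
  if (!length(res$lines)) return(empty_lexicon())
  parts <- strsplit(res$lines, "\t", fixed = TRUE)
  bad <- !lengths(parts) %in% c(3, 4)
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed lexicon row")
  unique(data.frame(
    surface = vapply(parts, `[`, "", 1), base = vapply(parts, `[`, "", 2),
    cat = vapply(parts, `[`, "", 3),
    features = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""),
    stringsAsFactors = FALSE))
}

lex_feature <- function(features, key) {
  m <- regmatches(features, regexec(paste0("(^|;)", key, "=([^;]*)"), features))[[1]]
  if (length(m) < 3) NA_character_ else m[3]
}

#' Read inference rules
#'
#' One rule per line in the form
#' `IF <X-TREATS-Y AND Z-PROCESS_OF-Y> THEN <X-TREATS-Z>`. Variables are
#' single upper-case letters bound by position; every variable in the
#' conclusion must appear in a premise.
#'
#' @inheritParams read_ontology
#' @return data.frame with columns `p1s,p1p,p1o,p2s,p2p,p2o,cs,cp,co`.
#' @export
read_inference_rules <- function(path, strict = FALSE) {
  res <- read_resource_lines(path, strict)
  empty <- data.frame(p1s = character(), p1p = character(), p1o = character(),
                      p2s = character(), p2p = character(), p2o = character(),
                      cs = character(), cp = character(), co = character(),
                      stringsAsFactors = FALSE)
  if (!length(res$lines)) return(empty)
  pat <- paste0("^IF *< *([A-Z])-([A-Z_]+)-([A-Z]) +AND +",
                "([A-Z])-([A-Z_]+)-([A-Z]) *> *THEN *< *([A-Z])-([A-Z_]+)-([A-Z]) *>$")
  m <- regmatches(res$lines, regexec(pat, res$lines))
  bad <- lengths(m) != 10
  if (any(bad)) resource_error(path, res$numbers, bad, "malformed inference rule")
  out <- empty[0, ]
  for (mm in m) {
    row <- as.list(mm[-1])
    names(row) <- c("p1s", "p1p", "p1o", "p2s", "p2p", "p2o", "cs", "cp", "co")
    if (!all(c(row$cs, row$co) %in% c(row$p1s, row$p1o, row$p2s, row$p2o))) {
      stop("conclusion variable not bound in a premise: ", paste(mm[1]), call. = FALSE)
    }
    out <- rbind(out, as.data.frame(row, stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Read a domain extension
#'
#' A YAML file with up to four terminological extension sections plus domain
#' relational resources: `semantic_types` (name/group pairs),
#' `blocked_mappings` (surface/concept id), `recontextualizations`
#' (concept id, old type, new type), `concepts` (new domain concepts with
#' synonyms), `ontology` (triples), and `rules` (indicator rules), the last
#' two in the same line dialects as the standalone files.
#'
#' @param path YAML file.
#' @return a list of class `domain_extension`.
#' @export
read_domain_extension <- function(path) {
  y <- yaml::read_yaml(path)
  as_domain_extension(y)
}

as_domain_extension <- function(y) {
  ext <- list(
    name = y$name %||% "extension",
    semantic_types = if (length(y$semantic_types)) {
      data.frame(type = vapply(y$semantic_types, `[[`, "", "type"),
                 group = vapply(y$semantic_types, `[[`, "", "group"),
                 stringsAsFactors = FALSE)
    } else data.frame(type = character(), group = character(), stringsAsFactors = FALSE),
    blocked_mappings = if (length(y$blocked_mappings)) {
      data.frame(surface = vapply(y$blocked_mappings, `[[`, "", "surface"),
                 id = vapply(y$blocked_mappings, `[[`, "", "id"),
                 stringsAsFactors = FALSE)
    } else data.frame(surface = character(), id = character(), stringsAsFactors = FALSE),
    recontextualizations = if (length(y$recontextualizations)) {
      data.frame(id = vapply(y$recontextualizations, `[[`, "", "id"),
                 old_type = vapply(y$recontextualizations, `[[`, "", "old_type"),
                 new_type = vapply(y$recontextualizations, `[[`, "", "new_type"),
                 stringsAsFactors = FALSE)
    } else data.frame(id = character(), old_type = character(), new_type = character(),
                      stringsAsFactors = FALSE),
    concepts = if (length(y$concepts)) {
      data.frame(id = vapply(y$concepts, `[[`, "", "id"),
                 name = vapply(y$concepts, `[[`, "", "name"),
                 semtypes = vapply(y$concepts, function(x)
                   paste(x$semtypes, collapse = ";"), ""),
                 source = "DOMAIN",
                 synonyms = vapply(y$concepts, function(x)
                   paste(x$synonyms, collapse = "|"), ""),
                 stringsAsFactors = FALSE)
    } else data.frame(id = character(), name = character(), semtypes = character(),
                      source = character(), synonyms = character(),
                      stringsAsFactors = FALSE),
    ontology = parse_ontology_lines(y$ontology %||% character()),
    rules = parse_rule_lines(y$rules %||% character())
  )
  class(ext) <- "domain_extension"
  ext
}

parse_ontology_lines <- function(lines) {
  lines <- as.character(unlist(lines))
  f <- tempfile(); on.exit(unlink(f))
  writeLines(lines, f)
  read_ontology(f, source = "DOMAIN", predicates = NULL) |>
    (\(x) { x$predicate <- toupper(x$predicate); x })()
}

parse_rule_lines <- function(lines) {
  lines <- as.character(unlist(lines))
  f <- tempfile(); on.exit(unlink(f))
  writeLines(lines, f)
  read_indicator_rules(f, source = "DOMAIN")
}

#' Apply a domain extension to a knowledge base
#'
#' Blocked mappings are removed from the dictionary index; recontextualized
#' concepts get their semantic type replaced; new semantic types, concepts,
#' ontological predications, and indicator rules are merged. The original
#' knowledge base is unmodified (copy semantics).
#'
#' @param kb a `predication_kb`.
#' @param extension a `domain_extension`.
#' @return a new `predication_kb`.
#' @export
apply_domain_extension <- function(kb, extension) {
  stopifnot(inherits(extension, "domain_extension"))
  for (id in extension$recontextualizations$id) {
    if (!id %in% kb$concepts$id) {
      stop("recontextualization targets unknown concept: ", id, call. = FALSE)
    }
  }
  for (id in extension$blocked_mappings$id) {
    if (!id %in% kb$concepts$id) {
      stop("blocked mapping references unknown concept: ", id, call. = FALSE)
    }
  }
  kb2 <- kb
  if (nrow(extension$semantic_types)) {
    kb2$semgroups <- unique(rbind(kb2$semgroups,
      stats::setNames(extension$semantic_types, c("type", "group"))))
  }
  if (nrow(extension$recontextualizations)) {
    for (i in seq_len(nrow(extension$recontextualizations))) {
      r <- extension$recontextualizations[i, ]
      row <- which(kb2$concepts$id == r$id)
      types <- strsplit(kb2$concepts$semtypes[row], ";", fixed = TRUE)[[1]]
      types[types == r$old_type] <- r$new_type
      kb2$concepts$semtypes[row] <- paste(unique(types), collapse = ";")
    }
  }
  if (nrow(extension$blocked_mappings)) {
    bm <- extension$blocked_mappings
    drop <- mapply(function(s, i) {
      normalize_surface(kb2$synonyms$surface) == normalize_surface(s) &
        kb2$synonyms$id == i
    }, bm$surface, bm$id)
    drop <- if (is.matrix(drop)) rowSums(drop) > 0 else as.logical(drop)
    kb2$synonyms <- kb2$synonyms[!drop, , drop = FALSE]
  }
  if (nrow(extension$concepts)) {
    newc <- extension$concepts[c("id", "name", "semtypes", "source")]
    kb2$concepts <- rbind(kb2$concepts, newc[!newc$id %in% kb2$concepts$id, ])
    for (i in seq_len(nrow(extension$concepts))) {
      syns <- strsplit(extension$concepts$synonyms[i], "|", fixed = TRUE)[[1]]
      syns <- syns[nzchar(syns)]
      if (length(syns)) {
        kb2$synonyms <- rbind(kb2$synonyms,
          data.frame(surface = syns, id = extension$concepts$id[i],
                     stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(extension$ontology)) kb2$ontology <- unique(rbind(kb2$ontology, extension$ontology))
  if (nrow(extension$rules)) kb2$rules <- unique(rbind(kb2$rules, extension$rules))
  rebuild_kb_indexes(kb2)
}

#' Read a knowledge base directory
#'
#' Expects the bundle layout written by [write_kb()]: `ontology.txt` (plus
#' optional `ontology_semnet.txt`), `indicator_rules.txt`, `concepts.tsv`,
#' `hierarchy.tsv`, `semgroups.tsv`, `gene_index.tsv`, `lexicon.tsv`,
#' `inference_rules.txt`, a `wordlists/` directory, and any
#' `extension_*.yaml` domain extensions.
#'
#' @param dir directory path.
#' @param strict passed through to the individual readers.
#' @return a `predication_kb`.
#' @export
read_kb <- function(dir, strict = FALSE) {
  p <- function(...) file.path(dir, ...)
  dict <- read_concept_dictionary(p("concepts.tsv"), strict)
  ontology <- read_ontology(p("ontology.txt"), source = "SUPPLEMENTARY", strict = strict)
  if (file.exists(p("ontology_semnet.txt"))) {
    ontology <- unique(rbind(
      read_ontology(p("ontology_semnet.txt"), source = "SEMANTIC_NETWORK", strict = strict),
      ontology))
  }
  wl <- list()
  wld <- p("wordlists")
  if (dir.exists(wld)) {
    for (f in list.files(wld, pattern = "\\.txt$")) {
      nm <- sub("\\.txt$", "", f)
      if (nm == "negation_triggers") {
        rows <- strsplit(read_resource_lines(file.path(wld, f), strict)$lines, "\t")
        wl[[nm]] <- data.frame(
          trigger = tolower(vapply(rows, `[`, "", 1)),
          direction = vapply(rows, function(r) if (length(r) > 1) r[2] else "pre", ""),
          stringsAsFactors = FALSE)
      } else {
        wl[[nm]] <- read_word_list(file.path(wld, f), strict)
      }
    }
    if (file.exists(file.path(wld, "comparative_scales.tsv"))) {
      wl$comparative_scales <- stats::setNames(
        read_two_col(file.path(wld, "comparative_scales.tsv"), c("cue", "scale"), strict),
        c("cue", "scale"))
    }
    if (file.exists(file.path(wld, "dysonyms.tsv"))) {
      wl$dysonyms <- stats::setNames(
        read_two_col(file.path(wld, "dysonyms.tsv"), c("surface", "id"), strict),
        c("surface", "id"))
    }
  }
  exts <- list()
  for (f in list.files(dir, pattern = "^extension_.*\\.ya?ml$")) {
    e <- read_domain_extension(p(f))
    exts[[e$name]] <- e
  }
  predication_kb(
    concepts = dict$concepts, synonyms = dict$synonyms,
    semgroups = read_semantic_groups(p("semgroups.tsv"), strict),
    hierarchy = read_hierarchy(p("hierarchy.tsv"), strict),
    ontology = ontology,
    rules = read_indicator_rules(p("indicator_rules.txt"), strict = strict),
    gene_index = if (file.exists(p("gene_index.tsv"))) read_gene_index(p("gene_index.tsv"), strict),
    lexicon = if (file.exists(p("lexicon.tsv"))) read_lexicon(p("lexicon.tsv"), strict),
    inference_rules = if (file.exists(p("inference_rules.txt")))
      read_inference_rules(p("inference_rules.txt"), strict),
    word_lists = wl,
    extensions = exts)
}

#' Write a knowledge base directory
#'
#' Serializes every component of the knowledge base to the canonical file
#' dialects, such that `read_kb(write_kb(kb, dir))` reproduces the bundle.
#' Output is deterministic (sorted within each file).
#'
#' @param kb a `predication_kb`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "wordlists"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  syn <- merge(kb$synonyms, kb$concepts, by = "id")
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", syn$surface, syn$id, syn$name,
                  syn$semtypes, syn$source)
  writeLines(sort(rows), p("concepts.tsv"))
  ont <- kb$ontology
  fmt_ont <- function(o) sort(sprintf("%s-%s-%s", o$subject_type, o$predicate, o$object_type))
  writeLines(fmt_ont(ont[ont$source != "SEMANTIC_NETWORK", ]), p("ontology.txt"))
  if (any(ont$source == "SEMANTIC_NETWORK")) {
    writeLines(fmt_ont(ont[ont$source == "SEMANTIC_NETWORK", ]), p("ontology_semnet.txt"))
  }
  writeLines(sort(format_indicator_rules(kb$rules)), p("indicator_rules.txt"))
  writeLines(sort(sprintf("%s\t%s", kb$hierarchy$child, kb$hierarchy$parent)),
             p("hierarchy.tsv"))
  writeLines(sort(sprintf("%s\t%s", kb$semgroups$type, kb$semgroups$group)),
             p("semgroups.tsv"))
  writeLines(sort(sprintf("%s\t%s\t%s", kb$gene_index$alias, kb$gene_index$gene_id,
                          kb$gene_index$symbol)), p("gene_index.tsv"))
  writeLines(sort(sprintf("%s\t%s\t%s\t%s", kb$lexicon$surface, kb$lexicon$base,
                          kb$lexicon$cat, kb$lexicon$features)), p("lexicon.tsv"))
  ir <- kb$inference_rules
  writeLines(sort(sprintf("IF <%s-%s-%s AND %s-%s-%s> THEN <%s-%s-%s>",
                          ir$p1s, ir$p1p, ir$p1o, ir$p2s, ir$p2p, ir$p2o,
                          ir$cs, ir$cp, ir$co)), p("inference_rules.txt"))
  wl <- kb$word_lists
  for (nm in c("empty_heads", "relational_nouns", "pseudo_negation",
               "coordination_barriers", "relativizers", "anaphor_determiners",
               "dysonym_exceptions", "nonprep_subject_nouns")) {
    writeLines(sort(wl[[nm]]), p("wordlists", paste0(nm, ".txt")))
  }
  writeLines(sort(sprintf("%s\t%s", wl$negation_triggers$trigger,
                          wl$negation_triggers$direction)),
             p("wordlists", "negation_triggers.txt"))
  writeLines(sort(sprintf("%s\t%s", wl$comparative_scales$cue, wl$comparative_scales$scale)),
             p("wordlists", "comparative_scales.tsv"))
  writeLines(sort(sprintf("%s\t%s", wl$dysonyms$surface, wl$dysonyms$id)),
             p("wordlists", "dysonyms.tsv"))
  for (e in kb$extensions) {
    yaml::write_yaml(domain_extension_to_yaml(e),
                     p(paste0("extension_", e$name, ".yaml")))
  }
  invisible(dir)
}

format_indicator_rules <- function(rules) {
  if (!nrow(rules)) return(character())
  cue <- ifelse(is.na(rules$cue_role), "none",
         ifelse(rules$cue_word == "BETWEEN_AND", "between-and",
                sprintf("%s(%s)", rules$cue_word, rules$cue_role)))
  sprintf("%s:%s:%s ->%s%s", rules$lexeme, rules$pos, cue, rules$predicate,
          ifelse(rules$inverse, " !inverse", ""))
}

domain_extension_to_yaml <- function(e) {
  list(
    name = e$name,
    semantic_types = apply_rows(e$semantic_types, function(r) list(type = r$type, group = r$group)),
    blocked_mappings = apply_rows(e$blocked_mappings, function(r) list(surface = r$surface, id = r$id)),
    recontextualizations = apply_rows(e$recontextualizations, function(r)
      list(id = r$id, old_type = r$old_type, new_type = r$new_type)),
    concepts = apply_rows(e$concepts, function(r)
      list(id = r$id, name = r$name,
           semtypes = as.list(strsplit(r$semtypes, ";", fixed = TRUE)[[1]]),
           synonyms = as.list(strsplit(r$synonyms, "|", fixed = TRUE)[[1]]))),
    ontology = as.list(sprintf("%s-%s-%s", e$ontology$subject_type,
                               e$ontology$predicate, e$ontology$object_type)),
    rules = as.list(format_indicator_rules(e$rules))
  )
}

apply_rows <- function(df, f) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) f(df[i, ]))
}
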