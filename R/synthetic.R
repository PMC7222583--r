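# Synthetic full-scale resource files. The production-scale ontology and
# indicator-rule files are license-gated; this generator writes a
# deterministic synthetic scale model with the documented summary profile so
# the loaders and the statistics machinery can be exercised at full scale:
# 7398 ontological predications (3100 semantic-network + 4298 supplementary)
# over 25 associative predicates, and 1366 indicator rules (1256
# single-word, 105 phrase/clausal, 5 modifier-head), with 195
# INTERACTS_WITH rules and 6 MEASURES rules. The content (type names,
# lexemes) is synthetic; only the shape and the counts model the real
# resources.

synthetic_rule_quota <- function() {
  preds <- ASSOCIATIVE_PREDICATES
  quota <- stats::setNames(rep(0L, length(preds)), preds)
  quota["INTERACTS_WITH"] <- 195L
  quota["MEASURES"] <- 6L
  rest <- setdiff(preds, c("INTERACTS_WITH", "MEASURES"))
  remaining <- 1366L - 195L - 6L
  base <- remaining %/% length(rest)
  quota[rest] <- base
  leftover <- remaining - base * length(rest)
  if (leftover > 0) quota[rest[seq_len(leftover)]] <- quota[rest[seq_len(leftover)]] + 1L
  quota
}

#' Write a synthetic full-scale reference knowledge bundle
#'
#' Deterministically generates `synthetic_ontology_semnet.txt` (3100
#' triples), `synthetic_ontology_supplementary.txt` (4298 triples), and
#' `synthetic_indicator_rules.txt` (1366 rules) in the canonical file
#' dialects. The files are a synthetic scale model for loader and
#' statistics validation; their vocabulary is generated, not drawn from any
#' terminology.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, a list of the three file paths.
#' @export
write_synthetic_reference_kb <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  types <- sprintf("Synthetic Type %03d", 1:90)
  preds <- ASSOCIATIVE_PREDICATES
  total <- 7398L
  per_pred <- total %/% length(preds)
  extra <- total - per_pred * length(preds)
  lines <- character(total)
  k <- 0L
  for (pi in seq_along(preds)) {
    n <- per_pred + (pi <= extra)
    for (j in seq_len(n)) {
      s <- types[((j - 1L) %% length(types)) + 1L]
      o <- types[(((j - 1L) %/% length(types) + j + pi) %% length(types)) + 1L]
      k <- k + 1L
      lines[k] <- sprintf("%s-%s-%s", s, preds[pi], o)
    }
  }
  stopifnot(k == total, !anyDuplicated(lines))
  p_sem <- file.path(dir, "synthetic_ontology_semnet.txt")
  p_sup <- file.path(dir, "synthetic_ontology_supplementary.txt")
  writeLines(lines[1:3100], p_sem)
  writeLines(lines[3101:7398], p_sup)
  quota <- synthetic_rule_quota()
  rules <- character()
  poses <- c("verb", "noun", "prep", "adj")
  counter <- 0L
  phrase_left <- 105L
  pred_idx <- 0L
  for (pred in names(quota)) {
    pred_idx <- pred_idx + 1L
    for (j in seq_len(quota[[pred]])) {
      counter <- counter + 1L
      if (j == 1L && pred_idx <= 5L) {
        # one structural rule per predicate keeps the five MOD_HEAD rules distinct
        rules <- c(rules, sprintf("MOD_HEAD:MOD_HEAD:none ->%s", pred))
      } else if (phrase_left > 0L) {
        rules <- c(rules, sprintf("syn trigger %04d:noun:none ->%s", counter, pred))
        phrase_left <- phrase_left - 1L
      } else {
        pos <- poses[(counter %% length(poses)) + 1L]
        rules <- c(rules, sprintf("syntrigger%04d:%s:none ->%s", counter, pos, pred))
      }
    }
  }
  stopifnot(length(rules) == 1366L, !anyDuplicated(rules))
  p_rules <- file.path(dir, "synthetic_indicator_rules.txt")
  writeLines(rules, p_rules)
  invisible(list(semnet = p_sem, supplementary = p_sup, rules = p_rules))
}
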