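# Evaluation harness: precision/recall/F1 of extracted predications against
# a gold standard of entity-pair relations, with the matching criteria used
# for causal chemical-disease benchmarks: an argument matches a gold entity
# on identifier, preferred name, or mention string, and a more specific
# concept (hierarchy descendant) also counts as a match; extracted
# predications whose arguments match a gold pair but whose predicate
# opposes the gold relation type count as false positives.

#' Evaluate predications against a gold standard
#'
#' @param predicted data.frame of predications as returned by
#'   [predications()] (columns `subj_id`, `subj_name`, `obj_id`,
#'   `obj_name`, `predicate` are used).
#' @param gold data.frame with columns `subj_id`, `obj_id` (and optionally
#'   `subj_name`, `obj_name`) of annotated relation pairs.
#' @param predicates predicate labels counting as asserting the gold
#'   relation (e.g. the causal set CAUSES, AFFECTS, AUGMENTS, STIMULATES,
#'   PREDISPOSES, ASSOCIATED_WITH).
#' @param opposing predicate labels that contradict the gold relation
#'   (e.g. TREATS, PREVENTS, and the negated counterparts of the causal
#'   predicates).
#' @param kb optional `predication_kb`; when supplied, a predicted argument
#'   that is a hierarchy descendant of the gold entity also matches.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_predications <- function(predicted, gold,
                                  predicates = c("CAUSES", "AFFECTS", "AUGMENTS",
                                                 "STIMULATES", "PREDISPOSES",
                                                 "ASSOCIATED_WITH"),
                                  opposing = c("TREATS", "PREVENTS"),
                                  kb = NULL) {
  opposing <- unique(c(opposing, paste0("NEG_", predicates)))
  arg_matches <- function(pid, pname, gid, gname) {
    if (identical(pid, gid)) return(TRUE)
    if (!is.null(gname) && !is.na(gname) &&
        tolower(pname) == tolower(gname)) return(TRUE)
    if (!is.null(kb) && is_ancestor(kb, gid, pid)) return(TRUE)  # more specific
    FALSE
  }
  pair_match <- function(p, g) {
    arg_matches(p$subj_id, p$subj_name, g$subj_id, g$subj_name %||% NA) &&
      arg_matches(p$obj_id, p$obj_name, g$obj_id, g$obj_name %||% NA)
  }
  asserting <- predicted[toupper(predicted$predicate) %in% predicates, , drop = FALSE]
  contradicting <- predicted[toupper(predicted$predicate) %in% opposing, , drop = FALSE]
  gold_hit <- rep(FALSE, nrow(gold))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(asserting))) {
    p <- as.list(asserting[i, ])
    hit <- FALSE
    for (g in seq_len(nrow(gold))) {
      if (pair_match(p, as.list(gold[g, ]))) {
        gold_hit[g] <- TRUE
        hit <- TRUE
      }
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  for (i in seq_len(nrow(contradicting))) {
    p <- as.list(contradicting[i, ])
    for (g in seq_len(nrow(gold))) {
      if (pair_match(p, as.list(gold[g, ]))) { fp <- fp + 1L; break }
    }
  }
  fn <- sum(!gold_hit)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall, f1 = f1)
}
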