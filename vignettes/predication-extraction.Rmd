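---
title: "Rule-based extraction of semantic predications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction of semantic predications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minipredicate)
```

## The problem and the model

Biomedical abstracts assert relationships — a drug treats a disease, an
infection causes a complication, a gene affects a process — in free text.
`minipredicate` turns sentences into *semantic predications*: subject–
PREDICATE–object triples whose arguments are concepts from a controlled
dictionary, each carrying semantic types (e.g. `Pharmacologic Substance`,
`Disease or Syndrome`), and whose predicate comes from a closed inventory of
25 associative relations plus `ISA` and four comparative predicates.

The system is rule-based and interpretable. Its central semantic constraint
is *ontology licensing*: an extracted associative predication is admissible
only if some (subject type, PREDICATE, object type) triple — an
*ontological predication* — is present in the bundled relation ontology.
Syntax proposes argument candidates; the ontology disposes.

The pipeline has five phases, run per sentence:

1. **Pre-linguistic analysis.** MEDLINE or plain-text parsing, rule-based
   sentence splitting with an abbreviation guard, tokenization that
   isolates hyphens and parentheses as tokens, and Schwartz–Hearst-style
   abbreviation detection (a bracketed short form is matched right-to-left
   against a preceding candidate expansion; detected short forms inherit
   the expansion's concept mappings for the rest of the document).
2. **Lexical/syntactic analysis.** Lexicon lookup (longest match,
   multi-word entries, homonymous records), part-of-speech disambiguation
   through a pluggable tagger hook with deterministic default rules, and a
   *minimal-commitment* shallow parser: barrier words (verbs, auxiliaries,
   modals, prepositions, conjunctions, complementizers) close the current
   chunk and open a new one; any chunk containing a noun is a simple NP
   (a PP when it starts with a preposition); the right-most noun is the
   head and everything except determiners (and punctuation, adverbs,
   numerals) is a modifier.
3. **Referential analysis.** Longest-match dictionary mapping with
   *dysonym* suppression (a synonym that is a word-level proper substring
   of the preferred name is spurious unless the residue consists of
   general terms like "procedure"; an explicit list covers non-substring
   cases), exact-match gene-alias mapping kept alongside dictionary
   mappings, optional domain extensions (new types, blocked mappings,
   recontextualized concepts, new concepts), and NegEx-style negated-
   mention flagging with a narrow window of two concepts.
4. **Post-referential analysis.** Empty-head marking (a generic head such
   as "variants" yields its semantic-head role to the modifier on its
   left), NP coordination (compatible conjuncts share a semantic group,
   a head word, or relational-noun status; series extend leftward across
   commas until a barrier), and optional sortal anaphora resolution.
5. **Relational analysis.** Hypernymic (`ISA`) and comparative
   predications by dedicated machinery, then indicator-rule trigger
   detection, class-specific argument identification, argument-reuse
   licensing with coordination distribution, negation, anaphora
   substitution, and sentence-level inference.

## The knowledge base

All resources are data, not code: a concept dictionary (one synonym per
row), a semantic-type → group table, a concept hierarchy, the relation
ontology, indicator rules (`lexeme:pos:cue ->PREDICATE`), a gene alias
index, a lexicon, inference rules, word lists, and domain extensions.
`read_kb()`/`write_kb()` round-trip a bundle directory; `fixture_kb()`
builds the miniature bundle the examples and tests run on.

The fixture bundle is a synthetic miniature: it contains exactly the
concepts, types, rules, and hierarchy edges that the bundled worked
examples exercise. Identifiers without an authoritative printed source are
synthetic (`C1000001` …). It emulates the *shape* of a production
terminology — ambiguity ("influenza" reaching both the disease and, before
suppression, a vaccine concept), multi-source mappings (dictionary plus
gene index for "Ataxin-10"), hierarchy depth for anaphora and hypernymy —
but none of its scale. Passing tests on it demonstrate the machinery, not
recall on real abstracts: real dictionaries bring millions of surface
forms, heavy ambiguity, and semantic-type noise that no fixture reproduces.

`write_synthetic_reference_kb()` complements it at the other end: a
deterministic, full-scale synthetic resource set (7398 ontology triples,
split 3100 semantic-network / 4298 supplementary; 1366 indicator rules
split 1256 single-word / 105 phrase / 5 modifier-head, with 195
`INTERACTS_WITH` and 6 `MEASURES` rules over 25 predicates) whose only
purpose is validating the loaders and statistics at realistic volume. Its
vocabulary is generated; only the counts model the real resources.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| negation window | 2 concepts | mentions flagged after (or before, for post-triggers) a trigger |
| hypernym BE window | 5 phrases | NP–BE–NP search span |
| anaphora search window | whole preceding document | nearest valid antecedent wins |
| abbreviation long-form bound | min(|sf|+5, 2·|sf|) words | standard short-form/long-form bound |
| coordination barriers | between, either, against, such as, including | terminate leftward extension |
| empty-head types | Qualitative/Quantitative/Functional/Temporal/Spatial/Idea or Concept | "non-informative" type set |

All word lists (empty heads, relational nouns, negation triggers,
pseudo-negation, anaphor determiners, comparative scales, dysonyms) are
open configuration seeded with their documented members; counts are never
hard-coded.

## Design choices made where the design was open

- **Coordinates** are 0-based half-open everywhere internally; serializers
  own any conversion.
- **Argument search order** is nearest-first, scanning outward from the
  indicator in the licensed direction; the first ontology-licensed
  (object, subject) pair wins. This deterministic order reproduces every
  bundled example without scoring machinery.
- **Inverse orientation.** Rules for locative/stative predicates
  (`LOCATION_OF`, `PROCESS_OF` via *with*, implicit-negative *lack*) are
  marked inverse-capable; when only the transposed triple is licensed,
  semantic roles follow the ontology triple rather than surface order
  ("infarction in the left internal capsule" → capsule `LOCATION_OF`
  infarction).
- **Nominal argument identification** uses a cued-first strategy with a
  licensed fallback: a cue-PP is tried first; if no licensed binding
  exists, the object falls back to the post-trigger *of*-PP chain and the
  subject to modifiers and a leftward scan. *Of* cues the subject only
  when the rule carries an obligatory object cue; *by/with/via*, commas,
  parentheses, and BE forms may cue subjects; a non-BE verb blocks the
  leftward subject scan (this is what keeps "drugs approved for the
  treatment of PAH" from yielding a predication in its own sentence while
  "the long-term use of these drugs for the treatment of patients with
  PAH" yields one). A configured class of nouns (*cause* and kin) rejects
  prepositionally cued subjects.
- **Argument reuse** is blocked unless licensed by (a) an overt
  relativizer after the NP, (b) a reduced relative — the NP immediately
  precedes a PP whose predication took it as an argument — or (c) the
  current indicator being that immediately following PP. When a conjunct
  is bound, parallel predications are emitted for every other conjunct
  whose types license the same role (coordination distribution).
- **Conjunct ban.** "Arguments may not be conjuncts" is enforced as:
  subject and object of one predication may not be co-conjuncts of the
  same coordination (unless the rule cue is between-and). The stricter
  reading — no conjunct is ever an argument — would make distribution
  impossible.
- **Negation.** Mention-level NegEx flags stop at clause boundaries
  (semicolon, colon, period, parentheses, *but*); "not as" is treated as
  pseudo-negation so equative comparatives ("not as effective as") are
  ranked, not negated. Predicate-scope negation requires the indicator to
  immediately follow the trigger or be separated only by adverbs and
  verbal-complex tokens. Implicit-negative rules flip to the positive
  predicate under textual negation; a double-`NEG_` form is never emitted.
- **Comparatives** implement two pattern families (stated comparison via
  *compare/comparison … with/to*; scaled comparison via *as ADJ as* and
  *more/less ADJ than*), with same-group compatibility and a cue → scale
  table (EFFECTIVENESS, SAFETY, POTENCY). The inventory is extensible
  configuration; compared terms are consumed for reuse purposes, while
  hypernym arguments are not (hypernym pairs live inside structures other
  machinery rarely touches).
- **Anaphora.** Candidate anaphors contain an indicating determiner or
  adjective; *the* is included so appositive filtering ("the gene,
  BRCA1") has scope to act. The antecedent's concept must be a strict
  hierarchy descendant of the anaphor's, with number agreement; a plural
  anaphor whose nearest antecedent is a conjunct resolves to all conjuncts
  (set membership). Pronominal anaphora is out of scope.
- **Inference** runs per sentence to a fixpoint with deduplication, so
  chains across inferred premises are permitted; conclusions must be
  ontology-licensed and are flagged. Anaphora-substituted predications
  participate via their extraction sentence.
- **Pipeline order** is fixed: hypernymy → comparatives → triggers →
  arguments (reuse inline) → negation → anaphora substitution →
  inference.
- **Ties.** Same-span concept candidates are broken by a pluggable hook
  (default: lexicographic identifier); mapping lists order by position,
  then match score, then source (dictionary before gene index), then
  identifier — the whole pipeline is deterministic, byte-identical across
  runs.

## Degenerate inputs

Empty documents produce empty output and exit status 0 from the CLI.
Sentences without dictionary hits produce sentence records only. Unmatched
alphabetic tokens receive a default noun reading (adverb for `-ly`), so
chunking never fails on out-of-lexicon material. Malformed resource lines
are reported with line numbers; unknown predicate labels and dangling
extension references are validation errors.

## What the tests cover, and at what size

The regression corpus is 17 curated sentences; property suites additionally
run 20–40 sentences from a seeded template generator per invocation
(templates instantiate the verbal, prepositional, nominal, coordination,
negation, and comparative structures with fixture synonyms). These sizes
keep the full suite under half a minute while covering every code path;
they were chosen as the smallest corpus that exercises each licensing and
reuse rule at least once. Invariants checked throughout: licensing
soundness, determinism, offset fidelity, negation involution, hypernym
group/hierarchy constraints, anaphora specificity, coordination
compatibility, and reuse licensing.

## Evaluation harness

`evaluate_predications()` computes precision/recall/F1 against a gold
standard of entity pairs with benchmark matching rules: identifier, name,
or mention match; a hierarchy-descendant (more specific) argument counts as
a match; an extracted predication whose arguments match an annotated pair
but whose predicate opposes the relation (e.g. `TREATS` against a causal
annotation, or a negated causal predicate) is a false positive. Corpus-
scale scores require externally licensed terminologies and corpora and are
intentionally not produced by this package's tests; the harness exists so
such an evaluation can be run when those resources are available.

## Known limitations

- Dictionary mapping is longest-match with a tie-break hook — no
  candidate scoring or word-sense disambiguation; the statistical taggers
  and gene recognizers that production systems embed are replaced by
  deterministic rules and an exact-match alias index behind the same
  interfaces.
- Verbal/clausal coordination, coordination ellipsis, pronominal
  anaphora, and cross-sentence relations beyond sortal anaphora are not
  addressed.
- The bundled knowledge base demonstrates machinery, not coverage; all
  quantitative behavior on real corpora depends on the resources supplied
  at run time.
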