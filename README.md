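# minipredicate

Rule-based extraction of **semantic predications** — subject–PREDICATE–object
triples over ontology concepts — from biomedical text, for text-mining
researchers and knowledge-graph builders who need interpretable,
deterministic relation extraction rather than a trained black box.

Given a sentence, the pipeline runs five phases: pre-linguistic analysis
(sentence splitting, tokenization, abbreviation detection), shallow
*minimal-commitment* parsing driven by barrier words, referential analysis
(dictionary concept mapping with dysonym suppression, gene-alias mapping,
negated-mention detection), post-referential analysis (empty-head marking,
NP coordination, optional sortal anaphora), and relational analysis. The
relational core maps lexical and structural triggers to predicates via
**indicator rules** (`treat:verb:none ->TREATS`,
`treatment:noun:with(subject) ->TREATS`, modifier-head rules), binds
arguments with class-specific syntactic rules, and admits a predication
only when an **ontological predication** — a licensed
(subject semantic type, PREDICATE, object semantic type) triple such as
`Pharmacologic Substance-TREATS-Disease or Syndrome` — supports it.
Negation, argument-reuse licensing with coordination distribution,
hypernymic (`ISA`) and comparative predications, sortal-anaphora
substitution, and sentence-level inference rules complete the model.

Every knowledge resource (concept dictionary, semantic groups, concept
hierarchy, relation ontology, indicator rules, lexicon, word lists, domain
extensions) is pluggable data; a miniature fixture bundle ships with the
package.

## Worked example

```r
library(minipredicate)
kb  <- fixture_kb()
res <- run_pipeline("MRI revealed a lacunar infarction in the left internal capsule.", kb)
cat(write_simplified(res), sep = "\n")
```

```
MRI revealed a lacunar infarction in the left internal capsule.
C0024485: Magnetic Resonance Imaging (Diagnostic Procedure)- diagnoses -C0333559: Infarction, Lacunar (Disease or Syndrome)
C2339807: Left internal capsule (Body Part, Organ, or Organ Component)- location_of -C0333559: Infarction, Lacunar (Disease or Syndrome)
```

Two predications: the verb *revealed* triggers `DIAGNOSES` with the
procedure as subject and the disorder as object, and the preposition *in*
triggers `LOCATION_OF` — bound in inverse orientation, because only
`Body Part, Organ, or Organ Component-LOCATION_OF-Disease or Syndrome` is
licensed, so the anatomical concept becomes the semantic subject even
though it follows the disorder in the sentence.

With the optional sortal-anaphora stage, generic arguments are replaced by
their antecedents:

```r
text <- paste(
  "There are currently 3 classes of drugs approved for the treatment of PAH:",
  "prostacyclin analogues, endothelin receptor antagonists, and",
  "phosphodiesterase type 5 inhibitors.",
  "The current evidence supports the long-term use of these drugs",
  "for the treatment of patients with PAH.")
predications(run_pipeline(text, kb, run_options(anaphora = TRUE)))[, c("subj_name", "predicate", "obj_name")]
```

```
                       subj_name predicate                        obj_name
1                   Epoprostenol    TREATS Pulmonary arterial hypertension
2 Endothelin receptor antagonist    TREATS Pulmonary arterial hypertension
3  Phosphodiesterase 5 inhibitor    TREATS Pulmonary arterial hypertension
```

Without the stage, the same passage yields one generic predication
(`Pharmaceutical Preparations TREATS Pulmonary arterial hypertension`).

Output is available as simplified plain text (`write_simplified()`), a
pipe-delimited full-fielded format with offsets, scores, and indicator
types (`write_full_fielded()`), and XML (`write_xml_output()`). A thin
command-line driver wraps the same functions:

```sh
Rscript inst/cli/minipredicate.R run --input abstract.txt --output-format simplified
Rscript inst/cli/minipredicate.R kb stats
```

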