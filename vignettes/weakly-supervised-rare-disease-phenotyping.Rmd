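---
title: "Weakly supervised rare-disease phenotyping from clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised rare-disease phenotyping from clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rarelink)
```

## The problem

Rare diseases are individually rare but collectively common, and they are
chronically under-captured by structured hospital data: an admission's ICD
code list often omits phenotypes that are stated plainly in the free-text
notes. Dictionary-based named-entity-recognition-and-linking (NER+L) tools
can surface candidate mentions of rare-disease concepts from notes at high
recall, but they resolve ambiguous surface forms with a corpus-level
most-frequent-sense prior. Short abbreviations are the canonical failure:
"HD" in a discharge summary is usually haemodialysis, a hospital day or a
drug strength suffix, yet a linker that has bound "HD" to Huntington disease
will emit that concept every time. The result is a candidate stream with
near-perfect recall and very poor precision.

`rarelink` implements a pipeline that keeps the high-recall candidate
stream and learns — without any manual annotation — a *phenotype
confirmation model* that filters it. Confirmed mentions are then mapped to
the Orphanet rare-disease ontology (ORDO) and aggregated to admissions,
where the text-derived cohort can be compared against the cohort derivable
from ICD-9 codes.

## Pipeline overview

A *candidate link* is one potential assertion that a document mentions a
rare-disease concept: a character span `[m_start, m_end)` in a document, a
UMLS concept id, the context window around the mention, and the name of the
note section the mention sits in. For a document *d* and the rare-disease
UMLS vocabulary *O*, inference composes four stages:

1. **Candidates** — an upstream NER+L tool (or the built-in gazetteer
   stand-in) proposes mention–UMLS links, restricted to the rare-disease
   vocabulary.
2. **Representation** — each mention is encoded in its context window; the
   rows of a chosen encoder layer covering the mention's tokens are
   mean-pooled into a vector *v*.
3. **Confirmation** — a logistic model on *v* decides whether the link
   states a real phenotype of the patient.
4. **Ontology mapping** — confirmed UMLS concepts are mapped through the
   filtered UMLS-to-ORDO correspondence; the per-document union is the
   document's rare-disease concept set.

## Weak supervision: two rules, XNOR selection, AND labelling

Training labels for the confirmation model are created by two programmatic
rules over the candidate stream:

* **Mention-length rule (λ1)** — the mention has strictly more than `l`
  characters (default `l = 3`). Short surface forms are overwhelmingly
  ambiguous abbreviations.
* **Prevalence rule (λ2)** — the mention's concept accounts for strictly
  less than a fraction `p` of all candidate links (default `p = 0.005`).
  A concept that dominates the candidate stream is unlikely to be a rare
  phenotype every time; genuinely rare diseases are mentioned rarely.

A candidate enters the weak training set only when the rules *agree*
(XNOR): both satisfied → labelled positive, neither → labelled negative
(the labelling is the AND of the rules). Candidates on which the rules
disagree are left unlabelled; at evaluation time these form the "unseen"
strata, which test whether the trained model generalises beyond its own
labelling rules. Both inequalities are strict, read literally from their
definitions. `weak_label_dataset()` implements the partition;
`rules_only_predict()` exposes the separate recall-oriented OR of the two
rules used as a rules-only baseline, and `tune_rule_params()` grid-searches
`l` and `p` against a labelled validation set (ties break toward higher
recall, then larger `p`, then smaller `l`, then grid order — deterministic
and recall-biased).

Frequencies for λ2 are computed once over the full rare-restricted
candidate list of the corpus, not per document.

## Contextual mention representation

The encoder is pluggable: any deterministic function from input text to a
token table (with character offsets) plus a stack of hidden-layer matrices
satisfies the backend contract. Feature extraction takes the **second-last
layer** of the stack — the top layer is specialised toward the encoder's
pre-training objectives, while the layer below it carries better contextual
features — and mean-pools the rows of the tokens overlapping the mention
span. Two encoding strategies are exposed:

* `include_section` (default `TRUE`) prepends the section name and `": "`
  to the context, shifting the span bookkeeping accordingly (the delimiter
  is isolated in one constant);
* `mask_mention` (default `FALSE`) replaces the mention surface with the
  backend's mask token, forcing a purely contextual representation.
  Non-masked encoding with section names is the default because mention
  identity is itself informative.

Token–character alignment uses *overlap*, not containment: subword
tokenisers may merge mention boundaries with neighbouring characters, and
containment could yield an empty token range. If a backend declares a
maximum token length, inputs are truncated symmetrically around the mention
before encoding. Packaged backends: production adapters are expected to
wrap a pretrained clinical transformer; the shipped `stub_encoder()` is a
deterministic three-layer stand-in (hash-derived token identity, a
neighbour-mixing middle layer, and a rotated top layer) used by all tests.

## The confirmation model

`fit_confirmation_model()` is an L2-penalised binomial maximum-likelihood
fit computed by Newton/IRLS with the intercept unpenalised. The pinned
configuration — inverse regularisation strength `C = 1.0`, tolerance
`1e-4`, at most 100 iterations — is recorded in `train_meta` together with
the seed and a convergence flag, so a fit is reproducible across library
versions. Training uses a seeded subsample of at most `n = 9000` weakly
labelled pairs (`subsample_training()`); beyond that the additional weak
pairs change results very little. The decision rule is
`probability >= threshold` with `threshold = 0.5` by default — the tie goes
to the positive class, a deliberate recall-biased choice, and the threshold
is exposed because the method itself does not prescribe one. A model
trained on manually labelled pairs instead of weak labels is the same fit
with `provenance = "strong"`.

## Ontology matching

Cross-references arrive as preprocessed TSV triples ⟨ORDO concept, external
concept, relation⟩; parsing OWL or UMLS RRF distributions is a converter
concern outside this package. Two filters guard precision:

* only **E** (exact) and **BTNT** (broader-to-narrower) relations are
  trusted; **NTBT** (a broader external concept standing in for a narrow
  rare disease, e.g. common hyperlipidemia for a rare hyperlipidemia
  subtype) is dropped;
* ORDO concepts under the **group-of-disorders** phenome class are
  excluded — their external mappings point at umbrella or common-disease
  concepts. The flag is an explicit boolean column; the package does not
  traverse the ORDO class hierarchy.

Cross-references whose ORDO id lacks metadata are dropped and counted —
fail-safe toward precision. A UMLS id mapped by several trusted
cross-references keeps the full set of ORDO targets. The ICD-9 baseline map
composes ICD-9→ICD-10 pairs with ICD10-system cross-references and
ICD-9→UMLS pairs with the UMLS map, unioning both paths and recording
which fired.

## Admission cohorts

Document-level concept sets are unioned over each admission's documents; a
document without an admission id is its own singleton admission. One
confirmed mention suffices to assign an admission-level phenotype,
consistent with union aggregation. `compare_cohorts()` counts, per ORDO
concept, the admissions found only by ICD codes, only by text, and by
both; the set-algebra identities `icd_only + both = |ICD|` and
`nlp_only + both = |NLP|` hold per concept by construction and are asserted
in the tests.

## The synthetic study

Because the clinical corpora this method targets are access-restricted, the
package ships a seeded generator (`generate_corpus()`,
`make_end_to_end_fixture()`) that reproduces the statistical structure the
method relies on, and nothing more:

* sectioned notes containing **long unambiguous rare-disease terms** and
  **short ambiguous abbreviations** whose true sense (disease vs
  non-disease) is carried by cue words injected into the surrounding
  window with probability `cue_strength` (default 1.0);
* a **skewed candidate frequency distribution**: at the standard scale,
  3 prevalent ambiguous concepts at ~21% of candidates each (far above
  `p = 0.005`) whose abbreviations are almost never the disease (1% of
  abbreviation occurrences), and 60 rare concepts at ~0.3% each, 20 of
  them with genuinely ambiguous abbreviations (50% disease sense);
* admission groupings of 1–3 documents and **under-coded ICD-9 lists**:
  each true admission phenotype is omitted from the code list with
  probability `icd_undercoding_rate` (default 0.5), mirroring how real
  code lists miss phenotypes that only the notes state;
* `negation_rate` (default 0) wraps disease mentions in negation templates
  and sets their upstream flag — negation detection itself is out of scope
  here, so these mentions exist to exercise the flag-dropping path.

Mention events are apportioned to concepts by largest-remainder quotas of
the frequency targets, so realised frequencies track their targets at any
seed instead of drifting across the prevalence threshold. Cue vocabularies
are disjoint across senses by construction (validated), which makes the
sense a linear function of the bag of neighbouring tokens — learnable by
mean pooling plus logistic regression, and hence the minimal structure
under which the weak-supervision benefit is observable at all.

What the generator does **not** emulate: clinical grammar, spelling noise,
section-dependent semantics, abbreviation senses that are themselves other
diseases, hypothetical/family-history mentions, or the long-tail vocabulary
of real notes. A pass on synthetic data therefore demonstrates the
machinery — rule partition, representation, filtering, mapping, cohort
algebra — under conditions where context determines sense; it does not
predict absolute performance on any real corpus.

Problem sizes: the `tiny` fixture (20 documents, 80 candidate links, 8
concepts) drives the unit tests; the `standard` fixture (1,200 documents,
4,800 candidate links, 63 concepts, seed 42) is the scale at which the
package's summary quantities are computed — large enough that the weak
partition has hundreds of positives and thousands of negatives, small
enough to run in seconds on one core.

## Numerical conventions and degenerate inputs

* Offsets are 0-based, end-exclusive, in Unicode code points everywhere.
* Word boundaries for the gazetteer are alphanumeric/non-alphanumeric
  transitions, so "HD" never fires inside "CHD"; matching is
  longest-match-first, left-to-right, non-overlapping.
* Precision and recall use the 0-when-undefined convention (empty
  prediction sets score 0, not NaN); F1 is 0 when both are 0.
* Evaluation is closed-world over the gold key set by default (annotation
  protocols label candidate pairs); `closed_world = FALSE` counts
  predictions outside the gold set as false positives, for gold standards
  extended by annotators beyond the candidate pool.
* Metrics are kept at full precision internally and rounded half-up to one
  decimal only when printed (base `round()` is round-half-even, which does
  not match how results tables are conventionally reported).
* An empty candidate list weak-labels to an empty dataset; a zero-length
  corpus makes prevalence undefined and raises an error rather than
  guessing.
* Both Fleiss' kappa and averaged-pairwise Cohen's kappa are provided for
  multi-rater agreement, since published multi-rater values rarely state
  which variant was used.

## A worked run

```{r}
fx <- make_end_to_end_fixture("tiny")
links <- restrict_to_rare(fx$corpus$gold_links, fx$rare_set)
links
```

The tiny corpus is small enough that every concept exceeds the default
prevalence threshold, so we widen `p` to 0.1 for the demonstration (the
rules are corpus-dependent by design):

```{r}
params <- weak_rule_params(l = 3, p = 0.1)
ds <- weak_label_dataset(links, params)
ds
```

Train on the weak labels, confirm the full candidate stream, and score it
against the generator's gold labels:

```{r}
train <- subsample_training(ds, n = 9000, seed = 42)
X <- encode_links(train$links, stub_encoder, fx$strategy)
model <- fit_confirmation_model(X, train$labels, seed = 42)

V <- encode_links(links, stub_encoder, fx$strategy)
confirmed <- confirm_links(links, V, model)

gold <- as.data.frame(links)
prf(gold, link_key_of(links), stratum = "baseline")   # unfiltered linker
prf(gold, link_key_of(confirmed), stratum = "confirmed")
```

The unfiltered baseline has perfect recall by construction and poor
precision; the confirmation model removes most false candidates at a small
recall cost. The same composition at the standard scale, together with the
cohort comparison against under-coded ICD lists, is what
`scripts/acceptance.R` recomputes.

## Limitations

* The weak rules are heuristics: a rare disease whose canonical surface
  form is a 3-character abbreviation is invisible to λ1, and a rare
  disease that dominates a specialised corpus violates λ2. The grid search
  exists precisely because `l` and `p` are corpus-dependent.
* The confirmation model is linear in the mention vector; senses that are
  not linearly separable in the chosen encoder layer need a stronger
  encoder, not a deeper classifier.
* Negation and experiencer handling is carried as an upstream flag, never
  computed here.
* Ontology-matching quality is bounded by the cross-reference tables
  supplied; the package filters relations but does not repair mappings.
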