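---
title: "Stand-off annotation, agreement and automatic baselines: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand-off annotation, agreement and automatic baselines: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annostore)
```

## The data model

A *collection* holds immutable documents (ordered named sections of plain
text), an ontology-agnostic concept registry, a label vocabulary, a team of
annotators, and an ordered list of annotation *rounds*. All annotations are
stand-off: they address the section text by 0-based, half-open character
offsets over the text exactly as ingested — no Unicode normalization, no
whitespace trimming — so an offset written today resolves to the same
characters forever. Surfaces are always recomputed from the text, and
re-validated against it on every load and import; a surface/slice mismatch
is a hard error, because silently accepting it would corrupt every
downstream statistic.

Five annotation types are stored per (annotator, document, round): mentions
(contiguous spans; overlap permitted, including with other annotators'
spans), concept links (a set of registry concepts per mention), relationships
(subject–predicate–object with at least one mention component and an
optional free-text predicate), assertions (concept-only triples at document
level), and labels (document classification from the collection's label
set). Discontinuous mentions are out of scope.

Every annotation has an *identity key* used uniformly by copy-skip,
import deduplication, consensus and diffs: a mention is its
(document, section, start, end) span; a concept link is the span plus the
concept id; a relationship is the triple of its component keys, where a
component's key is its concept id, its mention span key, or its free-text
predicate lower-cased and trimmed; an assertion is its (subject, predicate,
object) ids; a label is (document, label). Free-text predicates are
normalized only for identity — the stored and exported text keeps its
original casing and spacing.

Two mutation rules were genuinely open and are decided here:

* **Cascade on mention deletion.** Deleting a mention deletes every
  relationship that references it. The alternative — orphaned components —
  would leave stored relationships violating their own validity rule.
  Cascaded deletions are reported in the deletion report, never silent.
* **"Annotate all" matching.** All-occurrence annotation scans each section
  left to right with case-sensitive exact substring matching, non-overlapping
  (the scan resumes at match end); a case-insensitive flag is available. A
  token-boundary helper (`token_align()`, a token being a maximal run of
  non-space characters) is provided but never enforced, since the headless
  API collapses the interactive selection gestures into arbitrary valid
  offsets.

Rounds duplicate the previous round's annotations for carried-over members
and are thereafter isolated; the round-isolation tests serialize the prior
round canonically and require byte identity under hundreds of random edits
to the new round. Self-relations (subject and object the identical mention)
are permitted with a warning, as nothing in the model forbids them.

## Unitization and agreement

Kappa statistics need a fixed items-by-categories grid with a constant rater
count; free-form annotation provides neither, so a *unitization* step maps
each annotation type onto such a grid:

| type         | item                      | categories                 |
|--------------|---------------------------|----------------------------|
| mention      | span key                  | PRESENT / ABSENT           |
| concept link | (span key, concept id)    | PRESENT / ABSENT           |
| relationship | (subject key, object key) | predicate identity ∪ ABSENT|
| assertion    | (subject id, object id)   | predicate id ∪ ABSENT      |
| label        | (document, label)         | PRESENT / ABSENT           |

Items are the union of keys observed across the raters in scope; every rater
contributes exactly one category per item (ABSENT when they did not annotate
it), which restores the constant-`n` requirement. Keying relationships and
assertions by their endpoint pair makes their agreement measure *predicate
choice*, the decision annotators actually disagree on; if a rater holds
several predicates on one pair, the lexicographically smallest is taken,
deterministically. Span matching across annotators is exact — partial
overlap earns no credit; chance-corrected overlap measures (Krippendorff's
alpha and friends) are deliberately out of scope.

Collection-scope kappa *pools* items across documents (the document id is
part of every item key) rather than averaging per-document kappas; pooling
weights documents by how much was annotated in them and needs no convention
for undefined per-document values. Degenerate cases: an empty table is
undefined (`NA`); if every rater assigns every item identically the
observed agreement is 1 and kappa is defined as exactly 1, even when chance
agreement is also 1 and the ratio is formally 0/0 — perfect agreement is
perfect. Both kappas are validated against independently coded textbook
evaluations to 1e-12 on a thousand random tables, and against values frozen
from established external implementations on fixed tables.

Majority-vote consensus selects identity keys held by *more than half* of a
document's annotators, where the annotator count is the number of annotators
with at least one annotation of any type on that document in the round — not
the collection membership, so an invited-but-inactive member does not dilute
the vote. The machine annotator is excluded from the rater pool by default
(it is the baseline being judged, not a judge); a flag includes it. The
consensus is materialized under the reserved virtual annotator id `"IAA"` so
it can be loaded, copied and exported like a teammate's set.

## Interchange formats

Exports are deterministic: annotations are ordered by identity key, JSON key
order is fixed, and two exports of the same state are byte-identical. The
BioC dialect maps sections to passages with absolute offsets over the
concatenation of sections in canonical order joined by single newlines;
mentions become `annotation` elements whose ids are derived from the
identity-key sort order (stable across exports); relationships become
`relation` elements whose nodes reference those ids, with concept and
free-text components carried as infons; assertions — being concept-only —
become relations with zero nodes and their three components as infons, a
documented dialect choice since BioC relations normally reference
annotations. Because relation nodes need their annotations, a BioC export of
relationships always includes the mentions.

Imports are transactional: the whole file is validated on a working copy of
the store — spans in bounds, surfaces equal to the text slice, documents and
concepts known, labels in the vocabulary — and committed only if every
record passes. Records identical (by identity key) to annotations already
held are skipped and counted. When several annotation types are exported to
CSV, one file per type is written into a directory; each CSV carries a
`schema_version` column.

## The automatic-annotation pipeline

The pipeline keeps the shape *entity linking → sentence segmentation →
bag construction → bag-level prediction* (for document-level gene–disease
assertions) and *entity linking → sentence-level aspect scoring → rule
lookup* (for sentence-level gene-expression–cancer relationships), but the
predictors behind it are a pluggable scorer interface with deterministic
rule-based defaults. Trained neural models (piecewise-CNN bag classifiers,
transformer aspect models) are GPU-scale artifacts and are intentionally not
reimplemented; any scorer mapping a sentence to per-predicate scores in
[0, 1] can be plugged in, and scorer outputs violating the contract (missing
concept id, name or type on any component) are rejected before anything is
stored.

Entity linking is a dictionary scan: per lexicon, a deterministic
left-to-right longest-match pass (one concept per surface per lexicon;
overlap across lexicons allowed, overlap within a lexicon impossible by
construction). Sentences are split on `.?!` followed by whitespace and an
uppercase letter or digit, with a configurable abbreviation list; spans tile
the text, so offsets computed inside a sentence remain document offsets.
Bags collect, for each (gene, disease) pair, every sentence containing at
least one mention of each. Bag-level prediction averages the per-sentence
predicate scores — the score-level analogue of averaging sentence
representations, which is the meaningful counterpart when there is no neural
encoder — and emits the arg-max predicate, breaking ties by the fixed
vocabulary order (ties are counted and reported). The `NA` predicate means
"no association" and suppresses the bag's output. The gene–disease predicate
vocabulary is {Therapeutic, Biomarker, Genomic Alterations, NA}; the
gene-expression–cancer vocabulary is {biomarker, tumor suppressor,
oncogene}, inferred from three per-sentence aspects — change of gene
expression, change of cancer status, gene–cancer interaction — through a
rule table. The bundled default table encodes the minimal biologically
sensible mapping (expression change concordant with disease progression ⇒
oncogene; discordant ⇒ tumor suppressor; association without expression
change ⇒ biomarker); it is a configuration file, replaceable without code
changes, and no fidelity to any externally published rule set is claimed.

Automatic output is stored under the reserved annotator id `"AutoTron"`;
re-running replaces the previous machine set (idempotent refresh). The
provenance diff classifies a final set against this baseline by endpoint
pair: same predicate ⇒ confirmed, different predicate ⇒ updated, pair only
in the final set ⇒ added, only in the baseline ⇒ deleted. A relationship
whose endpoints changed is added + deleted, not updated — "update" is
reserved for the predicate (or, for concept links, the linked-concept set)
change. The four classes partition the pair-key universe by construction,
and the tests verify the partition on randomized edit scripts.

## The synthetic generator

The generator emulates the shape of a small expert annotation study: by
default ten template-assembled abstracts per task, three annotators, two
rounds. Documents are built from sentence templates, so every planted
mention offset is exact by construction and no NLP is needed to verify
anything; each planted association is expressed with in-lexicon surfaces and
an in-rule-table trigger within a single sentence, which makes the automatic
annotator's planted recall exactly 1.0 — a property of the construction,
used to test the pipeline's bookkeeping, not a claim about real text.
Annotator disagreement is injected by two probabilities: each annotator
keeps a gold annotation with `p_keep` (default 0.85) and swaps a kept
predicate to a random alternative with `q_swap` (default 0.25); the defaults
were chosen once to produce the moderate-to-low agreement regime typical of
relation-annotation studies and are not tuned thereafter. The two-round
study runs the automatic baseline, applies per-annotator edits, duplicates
the round, and lets each annotator adopt each strict-majority consensus
entry with probability `adoption` — full adoption drives round-2 kappa to
exactly 1 on consensus-covered items, zero adoption reproduces round-1 kappa
exactly, and intermediate adoption raises agreement in essentially all
seeded replicates, reproducing the qualitative round-2 improvement that
collaborative features are meant to deliver.

Everything is a pure function of the seed: each generator stage draws from
its own seed-derived substream (so adding a stage never reshuffles earlier
output), and generated collections carry a frozen timestamp so serialized
stores are byte-reproducible. What the generator does *not* emulate —
natural language variability, boundary ambiguity, lexical overlap between
entity names, annotator biases correlated across items — bounds what passing
tests show: they certify the statistics, the store algebra and the pipeline
plumbing, not performance on real abstracts.

## Numerical and engineering choices

* Offsets are `[start, end)`, 0-based, per section; BioC passage offsets are
  the only place absolute offsets appear.
* Timestamps are UTC ISO-8601, used for reporting only, never for identity.
* All randomized tests and the acceptance script fix their seeds; test
  problem sizes (a thousand random tables for the kappa oracles, fifty
  collections for round trips, a hundred replicates for the two-round
  trajectory, two hundred steps for round isolation) were chosen as the
  smallest sizes at which the properties are exercised across all code
  paths.
* The persistence layer is a directory per collection (metadata JSON,
  registry CSV, one JSON file per annotator/document/round) — a deliberate
  replacement of a relational backend to keep the artifact dependency-free;
  the CLI reads and writes the same layout.
* Importing a mention at a span the annotator already holds merges the
  concept sets rather than storing a same-span duplicate; two same-span
  mentions with different links are therefore collapsed by an
  export–import cycle, the one known deviation from strict round-trip
  identity (exercised fixtures do not produce such duplicates).

## Limitations

Agreement on spans is exact-match only; there is no partial-overlap credit
and no chance-corrected span-overlap coefficient. The unitization is one
defensible choice among several and is isolated behind `unitize()` so
alternatives can be substituted. The bundled scorers are keyword rules —
adequate as deterministic reference implementations and for pipeline
testing, not as biomedical relation extractors. Live bibliographic fetching
is specified as an injectable transport but no HTTP client is bundled, and
PDF parsing is declared as a third fetcher-style interface without a bundled
implementation.
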