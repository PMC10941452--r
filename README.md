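# annostore

A headless R toolkit for **stand-off annotation of biomedical text** by
multiple annotators over multiple rounds. It is aimed at teams building
annotated corpora for BioNLP tasks — relation extraction, entity linking,
topic labelling — who need a scriptable store for their annotations, honest
inter-annotator agreement numbers, and round-trip-safe interchange with the
formats the field uses (BioC-XML, JSON, CSV).

Annotations are *stand-off*: the text is immutable and every annotation
addresses it by 0-based half-open character offsets within a named document
section. Five annotation types are supported over an ontology-agnostic
concept registry (URI/ID + name + type + optional description):

* **mention** — a contiguous span; overlapping mentions are allowed;
* **concept link** — one or more registry concepts attached to a mention;
* **relationship** — a subject–predicate–object triple mixing mentions and
  concepts (at least one component must be a mention; the predicate may be
  free text);
* **assertion** — a document-level triple of pure concepts, unbound to any
  span;
* **label** — document classification from the collection's label set.

## Agreement statistics

For `n` raters, `N` unitized items and rater counts `n_ij` (item `i`,
category `j`), the package computes **Fleiss' kappa**

    P_i  = (sum_j n_ij^2 - n) / (n (n - 1))
    Pbar = mean_i P_i,   p_j = sum_i n_ij / (N n),   Pe = sum_j p_j^2
    kappa = (Pbar - Pe) / (1 - Pe)

and pairwise **Cohen's kappa** `(p_o - p_e) / (1 - p_e)`, both in `[-1, 1]`,
plus a **strict-majority consensus** (entries held by more than half of a
document's annotators) that can be materialized as a virtual annotator,
copied and exported. Free-form annotations are mapped onto the fixed
items-by-categories grid by a documented unitization: e.g. relationships are
itemized by their (subject, object) pair and categorized by the predicate, so
relationship agreement measures predicate choice.

The package also ships:

* readers for TXT / CSV / JSON documents and concept registries, plus an
  injectable fetcher contract for PubMed / Semantic Scholar / OpenAIRE
  metadata (tests use a fixture-backed stub, no network);
* a pluggable automatic-annotation pipeline (dictionary entity linking with
  longest-match scanning, rule-based sentence splitting, multi-instance bag
  construction, keyword/rule predicate scorers) for gene–disease association
  assertions and gene-expression–cancer association relationships, stored
  under the reserved machine annotator `"AutoTron"`;
* provenance diffs (`added` / `updated` / `deleted` / `confirmed`) of any
  final annotation set against a baseline such as the automatic one;
* seeded synthetic generators for corpora with planted associations and
  multi-annotator sets with controllable agreement;
* a CLI (`inst/cli/annostore`) exposing every operation as a subcommand.

## Worked example

```r
library(annostore)

coll <- create_collection("breast-ca", "BRCA1 pilot collection", "alice",
                          members = c("bob", "carol"),
                          labels = c("relevant", "not-relevant"))
register_concepts(coll, data.frame(
  identifier = c("GENE:672", "MESH:D001943", "MESH:D009369"),
  name       = c("BRCA1", "Breast Neoplasms", "Oncogenes"),
  type       = c("Gene", "Disease", "Predicate")))
add_document(coll, new_document("pubmed_27839516",
  c(abstract = "BRCA1 is an oncogene in breast cancer")))

# alice and bob annotate the same relationship; carol links a different concept
for (who in c("alice", "bob")) {
  subj <- create_mention(coll, who, "pubmed_27839516", "abstract", 0, 5,
                         concepts = "GENE:672")          # "BRCA1"
  obj  <- create_mention(coll, who, "pubmed_27839516", "abstract", 24, 37,
                         concepts = "MESH:D001943")      # "breast cancer"
  create_relationship(coll, who, "pubmed_27839516",
                      comp_mention(subj$id), comp_concept("MESH:D009369"),
                      comp_mention(obj$id))
}
create_mention(coll, "carol", "pubmed_27839516", "abstract", 24, 37,
               concepts = "MESH:D009369")

fleiss_agreement(coll, "concept")
#> Fleiss kappa [concept, collection, round 1]: -0.3500  (3 items, 3 raters)

summarize_annotations(coll)
#> Annotation statistics [global, collection, round 1]
#>   documents annotated: 1   annotators: 3
#>   mentions       5
#>   concept_links  5
#>   relationships  2
#>   assertions     0
#>   labels         0
#>   Fleiss' kappa by type:
#>     mention       -0.2000
#>     concept       -0.3500
#>     relationship  -0.5000
#>     assertion     UNDEFINED
#>     label         UNDEFINED
```

The concept kappa is negative: the three annotators agree on the spans but
split over which concept to link, and with only three items chance agreement
is high. The two concept links held by 2 of 3 annotators form the
strict-majority consensus (`majority_vote(coll, "pubmed_27839516",
"concept")`), which can be exported with `export_annotations(coll, "bioc",
annotator = "consensus")` or materialized as the virtual annotator `"IAA"`.

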