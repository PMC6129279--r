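---
title: "Rule-based consistency and prediction of regulatory phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based consistency and prediction of regulatory phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regphen)
```

## The problem

Gene products are annotated with Gene Ontology (GO) functions; loss-of-function
genotypes are annotated with phenotype classes from the Mammalian Phenotype
Ontology (MP) or the Human Phenotype Ontology (HPO). The two annotation layers
are curated independently, yet they are logically linked wherever a phenotype
class is *defined* as a change in the rate of a biological process. `regphen`
exploits this link in both directions: it audits function and phenotype
annotations for mutual contradictions, and it predicts regulatory phenotypes
for a loss of function directly from function annotations.

## The model

### Entity–Quality decomposition

Many phenotype classes carry logical definitions following the Entity–Quality
(EQ) pattern: an entity (here, a GO process or function) and a quality (a PATO
class). *Increased thymocyte apoptosis*, for instance, decomposes into the
entity *thymocyte apoptotic process* and the quality *increased rate*, further
constrained by the *abnormal* modifier. `decompose_phenotype_class()` reads
these definitions from `intersection_of` tag groups in OBO and returns a
(phenotype class, GO entity, direction) triple, with direction one of
`increased`, `decreased`, `abnormal`. The abnormal quality acts as a modifier:
a definition carrying both a directional quality and the abnormal quality is
directional (the abnormality merely distinguishes the phenotype from a
physiological change). A definition with qualities from both directional sets
is ambiguous and yields nothing, with a warning.

Which PATO classes mean what is configuration, not code: `quality_config()`
defaults to `PATO:0000912` (increased rate), `PATO:0000911` (decreased rate)
and `PATO:0000460` (abnormal), and accepts a YAML file for anything beyond
these. Entity recognition is by CURIE prefix (default `GO`).

### Regulation classes and the three rules

GO defines its regulation classes logically: *positive regulation of B cell
apoptotic process* is *biological regulation* that `positively_regulates` the
*B cell apoptotic process*. `index_regulations()` collects every class whose
logical definition carries a `positively_regulates` or `negatively_regulates`
differentia. The genus is unrestricted by default so that trimmed ontology
subsets whose definitions omit the genus still index; a `genus` argument
restores strictness.

Three meta-rules connect the two decompositions, reasoning about a *loss* of
the annotated function:

1. **inc_dec** — if a gene product positively regulates process P, its loss
   predicts the *decreased*-P phenotype;
2. **dec_inc** — if it negatively regulates P, its loss predicts the
   *increased*-P phenotype;
3. **abnormal** — if it is involved in P, its loss predicts the *abnormal*-P
   phenotype (unconditional on regulation structure).

`build_correspondence_rules()` materialises these as (function class,
phenotype class, rule kind) triples. `build_inconsistency_patterns()`
materialises the mirror pairs — positive regulator with the *increased*
phenotype, negative regulator with the *decreased* phenotype — which no
correctly annotated gene should instantiate. Rules are generated at the class
level only and never propagated along the hierarchy; subclass inference is a
matching-time choice (below), not a rule-generation choice, because an
annotation to a specific subclass does not carry the general implication of
its superclass.

### Consistency checking and prediction

`check_corpus()` joins each gene's direct function annotations against the
pattern list and its direct phenotype annotations against the patterns'
phenotype classes. In `exact` mode only identical phenotype classes match; in
`inferred` mode an annotation to a strict subclass of the pattern's phenotype
also matches and the asserted subclass is reported (`inferred_via`). Exact
findings are always a subset of inferred findings. Inference applies to the
phenotype side only by default, for the asymmetry argued above; a flag enables
function-side inference.

`predict_phenotypes()` applies the correspondence rules to direct function
annotations. Experimental annotations carry score 1.0; predicted-function
input (a gene, GO class, score TSV from any sequence-based predictor) passes
its scores through. When several functions license the same (gene, phenotype),
the maximum score wins — scores are confidences and max preserves the (0, 1]
contract; sum or mean would not. `split_novel()` partitions predictions into
already-asserted ("found", exactly or via a subclass-asserted phenotype) and
novel.

### Semantic similarity and evaluation

Information content is corpus-based: IC(c) = −log p(c) with p(c) the fraction
of annotated genes annotated to c after closure. Natural log is used; any
fixed base rescales all values uniformly and cannot change best-match rankings
or ROC results. Resnik similarity between classes is the IC of their most
informative common ancestor; gene–gene similarity is the Best-Match-Average
combination over the genes' direct phenotype sets. Normalisation divides the
whole matrix by its global maximum, so scores land in [0, 1] with at least one
1 whenever any similarity is nonzero.

Predictions are scored by the CAFA-style Fmax over a threshold grid
(default 0, 0.01, …, 1; the convention grid, since the metric's users do not
fix one). Both the truth sets and the per-threshold prediction sets are
closure-propagated before counting, consistent with superclass propagation in
the found/novel matching; a `propagate_predictions = FALSE` flag evaluates raw
sets. Ontology roots are excluded from both sets — closure makes them
trivially present. Precision is averaged over the genes with at least one
prediction at the threshold; recall over all genes of the evaluation set
(genes with at least one truth annotation and at least one prediction
anywhere on the grid). Interaction recovery is measured by ranking all scored
gene pairs by similarity and computing the ROC AUC with interacting pairs as
positives, via the rank-sum (Mann–Whitney) formulation with midrank ties —
identical scores earn half credit, so an all-tied ranking scores exactly 0.5.

## The synthetic study system

`fixture_spec()` + `make_toy_ontologies()` + `make_annotation_corpora()` +
`make_interaction_network()` generate a self-contained study system:

- a GO-like ontology (default 50 processes in a random DAG, 20 positive and
  20 negative regulation classes with logical definitions, each regulating a
  distinct process);
- an MP-like ontology with EQ definitions for a configurable fraction of
  processes (default all), three classes per covered process (abnormal,
  increased, decreased; the directional classes are subclasses of the
  abnormal one);
- corpora for (default) 100 genes, each with 1–3 function annotations and the
  rule-implied phenotypes, plus optional planted rule-violating pairs and
  random phenotype noise;
- an interaction network whose positives are sampled among phenotype-sharing
  pairs with configurable signal strength (2% of pairs by default).

The one-regulator-per-process constraint is deliberate: it guarantees that a
noise-free, violation-free corpus contains *no* pattern instance, so every
checker finding on noisy fixtures is attributable to the plant log. Random
DAGs sample parents among earlier classes, which guarantees acyclicity by
construction. Identical spec and seed give byte-identical serialised files.

What the fixtures do **not** emulate: the real GO/MP topology (depth, fan-out,
multiple inheritance density), multiple regulators per process, cross-species
class integration, annotation-extension contexts, and curation error modes
other than sign flips. Green tests therefore demonstrate correctness of the
machinery — joins, matching semantics, metric arithmetic — not performance on
real corpora, whose headline numbers depend on specific ontology and
annotation release versions.

## Numerical and design choices

- **Closure** is over `is_a` only, reflexive and cached per graph; `part_of`
  and other relationships never contribute to inference.
- **Tie-breaks** in prediction dedup are deterministic (score desc, rule kind,
  source function), and every serialised table is sorted, so reruns are
  byte-identical.
- **Degenerate inputs**: empty corpora propagate to empty results where a set
  is a valid answer (predictions, findings) and raise errors where a statistic
  is undefined (IC of an empty corpus, BMA of an empty set, Fmax with an empty
  evaluation set, ROC without both classes).
- **Fmax at m(t) = 0**: precision is undefined; the threshold contributes 0
  and the curve records `NA` precision.
- **Obsolete terms** are dropped at parse time with a warning and carry no
  edges.
- **Problem sizes** in the test suite (50-class similarity fixtures, 5-gene
  Fmax fixtures, 100-gene interaction fixtures with 20 null replicates) are
  chosen so that every brute-force oracle — matrix-power closure, double-loop
  joins, literal metric transliterations — remains exhaustive.

## Known limitations

- The OBO parser targets the tags the method needs (`id`, `name`, `is_a`,
  `relationship`, `intersection_of`, `is_obsolete`); it is not a full OBO 1.4
  round-tripper and does no OWL reasoning, so regulation classes lacking an
  asserted `intersection_of` definition are only found via the
  `use_relationship_fallback` flag.
- Nested EQ expressions are supported through pre-composed quality classes
  plus the quality table, not general class-expression parsing.
- Sign-neutral `regulates` definitions contribute to no rule.
- Cross-ontology similarity assumes the phenotype ontologies are already
  merged into one graph (as an integrated cross-species ontology provides).

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- fixture_spec(seed = 1, n_genes = 100, inconsistency_rate = 0.2)
onts <- make_toy_ontologies(spec)
regs <- index_regulations(onts$go)
decs <- decompose_phenotypes(onts$pheno)
rules <- build_correspondence_rules(regs, decs)
patterns <- build_inconsistency_patterns(regs, decs)
corp <- make_annotation_corpora(spec, rules, patterns)

findings <- check_corpus(corp$functions, corp$phenotypes, patterns, "exact")
pred <- predict_phenotypes(corp$functions, rules)
fmax(pred, corp$phenotypes, onts$pheno)
```
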