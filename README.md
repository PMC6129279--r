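# regphen

Rule-based validation and prediction of regulatory phenotypes from gene
function annotations.

## What it does, and for whom

Curators annotate gene products with Gene Ontology (GO) functions and
loss-of-function genotypes with phenotype classes (MP for mouse, HPO for
human). Wherever a phenotype class is logically *defined* as a changed rate
of a biological process, the two annotation layers constrain each other.
`regphen` is for ontology engineers, database curators and computational
biologists who want to exploit that constraint:

- **audit** corpora for genes whose function and phenotype annotations
  contradict each other (e.g. annotated to *positive regulation of B cell
  apoptotic process* while the knockout phenotype is *increased B cell
  apoptosis*);
- **predict** regulatory phenotypes for a loss of function directly from
  function annotations, experimental or computationally predicted;
- **evaluate** such predictions with CAFA-style Fmax and with
  similarity-based interaction recovery (ROC AUC).

Everything is testable offline: a synthetic-fixture generator emulates
GO-like and MP-like ontologies, GAF and phenotype files and STRING-like
interaction networks with planted, independently verifiable structure.

## The model

Phenotype classes with Entity–Quality definitions decompose into a GO
process E and a direction d ∈ {increased, decreased, abnormal}. GO
regulation classes decompose, via their logical definitions, into
(regulator R, process E, sign). Three meta-rules relate them under loss of
function:

| function of gene | predicted phenotype of its loss | rule kind |
|---|---|---|
| R `positively_regulates` E | decreased-rate E phenotype | `inc_dec` |
| R `negatively_regulates` E | increased-rate E phenotype | `dec_inc` |
| involved in E | abnormal E phenotype | `abnormal` |

The mirror pairs (positive regulator × increased phenotype, negative
regulator × decreased phenotype) are *inconsistency patterns*: a gene
co-annotated to both members of a pattern carries contradictory annotations.

Similarity uses IC(c) = −log p(c) (gene-frequency after ontology closure),
Resnik pairwise similarity Sim(c₁, c₂) = IC(MICA(c₁, c₂)), and the
Best-Match-Average combination for gene pairs. Predictions are scored by
Fmax = maxₜ 2·AvgPr(t)·AvgRc(t) / (AvgPr(t) + AvgRc(t)) over a 101-point
threshold grid, with precision averaged over genes that predict at a
threshold and recall over the whole evaluation set; interaction recovery is
the Mann–Whitney ROC AUC of similarity-ranked gene pairs.

## Worked example

```r
library(regphen)

spec <- fixture_spec(seed = 1, n_genes = 100, inconsistency_rate = 0.2)
onts <- make_toy_ontologies(spec)
rules    <- build_correspondence_rules(index_regulations(onts$go),
                                       decompose_phenotypes(onts$pheno))
patterns <- build_inconsistency_patterns(index_regulations(onts$go),
                                         decompose_phenotypes(onts$pheno))
corp <- make_annotation_corpora(spec, rules, patterns)

findings <- check_corpus(corp$functions, corp$phenotypes, patterns, "exact")
head(findings[, 1:4], 3)
#>    gene function_class phenotype_class violated_rule
#> 1 g0016     GO:3000011      MP:3000044       dec_inc
#> 2 g0021     GO:3000009      MP:3000002       dec_inc
#> 3 g0024     GO:3000015      MP:3000039       dec_inc
```

The fixture planted 20 rule-violating annotation pairs among the 100 genes;
the checker reports exactly those 20 (here: gene g0016 is annotated with a
negative regulator, GO:3000011, of a process whose *decreased*-rate
phenotype, MP:3000044, it is also annotated with — the mirror of what a loss
of function should produce).

```r
pred <- predict_phenotypes(corp$functions, rules)
head(pred, 3)
#>    gene phenotype_class score rule_kind source_function
#> 1 g0001      MP:2000002     1   dec_inc      GO:3000009
#> 2 g0002      MP:1000006     1  abnormal      GO:1000006
#> 3 g0002      MP:1000032     1  abnormal      GO:1000032

fmax(pred, corp$phenotypes, onts$pheno)
#> <fmax_result> Fmax = 0.9551 at t = 0 (n = 100 genes)

ic  <- information_content(corp$phenotypes, onts$pheno)
sim <- gene_similarity_matrix(corp$phenotypes, ic, onts$pheno)
net <- make_interaction_network(spec, corp$phenotypes, signal = 1)
roc_auc(similarity_pairs(sim), net$positives)
#> <roc_result> AUC = 0.9685 (99 positives / 4851 negatives)
```

Fmax is below 1 because the planted inconsistent phenotypes are part of the
truth but not predicted by the rules; the AUC shows that phenotype
similarity ranks the planted (phenotype-sharing) interaction partners far
above random pairs.

Real data flow through the same surface: `parse_obo()` for GO/MP/HPO,
`parse_gaf()` (evidence-code, NOT-qualifier and annotation-extension
filtering), `parse_phenotype_tsv()` (MGI and HPO dialects),
`parse_predicted_functions()` for scored function predictions,
`parse_string_links()` for interaction networks, and `run_pipeline()` /
`inst/cli/regphen.R` to orchestrate the whole workflow from a YAML config.

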