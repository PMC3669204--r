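---
title: "Methods: hybrid relative specificity similarity over ontology DAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid relative specificity similarity over ontology DAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrss)
```

## The problem

Gene Ontology annotations place gene products in three directed acyclic
graphs (biological process, cellular component, molecular function) whose
terms are linked by subsumption. Two proteins that act in the same process,
or in the same compartment, tend to interact; orthologs tend to keep their
function. Turning those tendencies into numbers requires a similarity
measure over the DAG that respects both the hierarchy *above* a term pair
(how specific is what they share?) and the hierarchy *below* it (how
general are the terms themselves?).

Purely edge-based measures are hostage to the DAG's topology: they treat
all edges as equal semantic steps and all terms at a depth as equally
specific, which real ontologies violate freely. Purely node-based measures
(Resnik and its variants) use corpus information content but ignore term
generality. HRSS keeps the three-component skeleton of the edge-based RSS
measure and replaces its edge counts with information content, so both
hierarchy directions and corpus usage inform the score.

## Model

Information content of a term $c$ in an annotation corpus:

$$IC(c) = -\log p(c), \qquad
  p(c) = \frac{\#\{\text{genes annotated to } c \text{ or a descendant}\}}
              {\#\{\text{annotated genes in the namespace}\}}$$

after closing every gene's annotations under ancestors (the true path
rule). $IC$ is computed per namespace; the root has $p = 1$, $IC = 0$;
terms never used have no defined IC and are excluded rather than
imputed.

For terms $t_i, t_j$ with most informative common ancestor (MICA):

* $\alpha_{IC} = IC(\mathrm{MICA})$ — specificity of the shared ancestry;
* $\beta_{IC}$ — mean of the two terms' generalities, each the IC gap
  $IC(\mathrm{MIL}) - IC(t)$ to the term's most informative *annotated*
  leaf descendant (leaves and terms with no annotated descendant leaf get
  0: they are maximally specific already);
* $\gamma = (IC(t_i) - \alpha_{IC}) + (IC(t_j) - \alpha_{IC})$ — the
  IC distance of the pair from the MICA.

$$\mathrm{HRSS}(t_i, t_j) = \frac{1}{1 + \gamma}
  \times \frac{\alpha_{IC}}{\alpha_{IC} + \beta_{IC}}$$

The edge-based RSS is the same skeleton with the MRCA's depth as
$\alpha$, the mean distance to the closest descendant leaf as $\beta$,
edge distance to the MRCA as $\gamma$, and a
$maxDepth/(maxDepth+\gamma)$ damping in place of $1/(1+\gamma)$. Both lie
in $[0, 1]$.

Gene products are compared either by aggregating the term-pair score
matrix of their annotation sets — MAX (global maximum) or BMA (mean of the
pooled row and column maxima, a $(|T_P|+|T_Q|)$-denominator form) — or by
the groupwise simUI/simGIC, the (IC-weighted) Jaccard of the propagated
term sets.

### Assumptions

* Annotation counts are over distinct gene products, not annotation rows.
* The corpus and the query terms come from the same ontology release; alt
  ids are resolved at parse time, obsolete terms carry no edges.
* Scores are only comparable within a namespace and a corpus; ICs computed
  under different log bases must not be mixed (the base is recorded in the
  `ic_table`).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `relations` | `is_a` | The conservative true-path core; `part_of` is a flag because the reference analysis never states which relations it traverses, and adding it changes ancestor sets, hence every downstream quantity. |
| `base` (IC log) | natural log | Ratios of ICs ($\gamma$ relative to $\alpha_{IC}$ enters additively, so HRSS is *not* base-invariant) — the base is a real modelling choice. Tests use base 2 because the toy corpus counts are dyadic, making hand-derived values exact. |
| `exclude_evidence` | none | The two reference conditions are "all evidence" and "excluding IEA"; any code set can be excluded. |
| pairwise term sets | direct annotations | Standard practice for MAX/BMA; propagated sets are available (`use_propagated`) since the reference is silent. Root-only annotations are removed — a root annotation says nothing. |
| universe | per namespace | All evaluations are per-ontology; a global universe would deflate $p(c)$ in small namespaces. |
| threshold rule | score ≥ t | Fixed convention so TPR/FPR tables reproduce. |
| `reps` (Z-score) | 1000 | The reference randomization count; the null permutes the full second column without excluding the true pairing. |

## Numerical and tie-break choices

* **MRCA/MICA ties** break to the lexicographically smallest term id. Any
  deterministic rule works; determinism is what matters for testing.
* **Zero-IC MICA** (terms sharing only the root): all IC-based
  similarities return 0 instead of erroring — a shared ancestor carrying
  no information is no evidence of similarity.
* **Lin 0/0** (both terms at IC 0) is defined as 0; **Jiang** distance is
  mapped through $1/(1+d)$ to $(0, 1]$, the common convention in the
  comparison literature, and the normalization is recorded in the score
  metadata.
* **`maxDepth`** is the maximum term depth of the namespace. In any DAG
  whose deepest terms are leaves this equals the maximum root-to-leaf
  shortest path; defining it over all terms keeps the invariant
  `maxDepth >= depth(t)` even for pathological DAGs where a non-leaf
  out-deepens every leaf via a shortcut edge.
* **Distances** are shortest paths through common ancestors only
  (upward edges), matching the MRCA-path decomposition of $\gamma$; the
  root depth is 0 and all distances are edge counts.
* **ROC sweep** uses the descending unique scores plus a sentinel above
  the maximum, so the curve always contains $(0,0)$ and $(1,1)$; AUC is
  the trapezoidal integral, which the tests verify equals the
  Mann–Whitney statistic with ties counted one half. Youden and F1
  maximizers break ties toward the smaller threshold.
* **Degenerate inputs** error with classed conditions
  (`hrss_degenerate_input`, `hrss_missing_ic`, `hrss_unannotated_gene`,
  ...) rather than returning silent zeros.

## What the synthetic data emulates — and what it does not

`toy_ontology_T()`/`toy_corpus_F()` form a fixed six-term, eight-gene
world whose IC values are exact binary logs; every measure's value on it
was derived by hand, so the equation-fidelity tests are exact to floating
point, not approximate.

`random_benchmark()` emulates the *construction logic* of a
protein-interaction benchmark: a layered DAG (root, branch, mid, deep,
leaf levels) partitioned into top-level branch lineages that meet only at
the root, genes concentrated near-evenly on a bounded set of deep "home"
leaves (plus occasional shallow noise annotations, 20% IEA evidence),
positives sharing a home leaf, negatives drawn from the enumerated pool
of cross-lineage pairs — which therefore share no ancestor below the
root — equal set sizes, fully seeded.  The balanced lineage assignment
and the even gene-to-cluster assignment are what make both pair pools
feasible at every seed, not just lucky ones. Defaults (30 terms, 40
genes, 50+50 pairs) keep the suite fast while leaving the DAG non-trivial
(multiple inheritance, unannotated terms).

It does **not** emulate the scale, depth distribution, annotation
sparsity, or inter-measure disagreements of the real GO corpora. By
construction positives share a high-IC term, so HRSS(MAX) separates the
classes almost perfectly (AUC ≈ 1 against the required > 0.9). A green
benchmark test therefore establishes that the pipeline wires together
correctly, that thresholding agrees with brute force, and that
randomization statistics behave — not that any measure would achieve a
particular AUC on a real interactome, and the published headline AUCs are
deliberately not asserted anywhere.

## Design choices where the design was open

* The score combination formulas follow directly from the component
  definitions: damp the specificity ratio by the pair's divergence from
  the common ancestor. Every worked example in the test suite reproduces
  the hand-derived values exactly under this reading.
* "Most informative leaf" is read as the annotated descendant leaf of
  maximal IC, so $\beta_{IC}$ is the largest IC gap to an annotated leaf.
* BMA uses the pooled-mean form; the half-sum-of-two-averages variant can
  be computed from the same matrix via `bma_strategy()` on the transposed
  halves if ever needed.
* The permutation null keeps accidental true pairs (no fixed-point
  exclusion), matching the reference's own observation that a randomized
  set contains a small number of true pairs on average.
* Whether ROC thresholds sweep unique scores or a fixed grid was
  unstated; unique scores lose no information and make the brute-force
  comparison exact.

## Known limitations

* Single-MICA only: disjunctive common ancestors (GraSM/DiShIn-style) are
  out of scope, as are TCSS, Wang's measure and Schlicker's relevance.
* No OWL input, no cross-namespace edges, no GO-slim mapping.
* IC is undefined for unannotated terms; queries touching them error
  rather than back off to a smoothed estimate.
* The CLI reads whole files into memory; it is sized for
  annotation-corpus-scale inputs, not for streaming.
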