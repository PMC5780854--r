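---
title: "Cross-ontology term similarity from network information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ontology term similarity from network information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infacront)
```

## The problem

Biomedical ontologies — the Gene Ontology's sub-ontologies, the Disease
Ontology, the Human Phenotype Ontology — each organize their own terms in
an IS_A hierarchy, but almost no relationships are curated *between*
ontologies. Because most ontologies annotate genes, a term pair drawn from
two different ontologies can still be compared through the genes the two
terms annotate. The classical vector-space model (VSM) does exactly that:
it represents each term by its annotated gene set and takes the cosine.
VSM treats genes as independent, so two terms annotating different but
functionally coupled genes score zero.

This package scores such pairs by letting information *flow* through a
gene functional-interaction network (GFIN): two terms are similar when a
random walker starting from one term's genes tends to reach the other
term's genes through the network, not only when the gene sets intersect.

## The model

**Weights (step 1).** Annotations (GAF records, IEA evidence excluded by
default, NOT-qualified records dropped) are propagated to IS_A ancestors:
if a gene is annotated by a term it is annotated by every ancestor. On the
propagated set, a term–gene pair is weighted
$w(t_i, g_j) = -\log_2(n_j / N_T)$, where $n_j$ is the number of terms
annotating gene $g_j$ and $N_T$ the total number of annotation terms: a
gene annotated everywhere says little about any one of its terms. Each
term is weighted $w(t_i) = -\log_2(n_g / N_G)$ with $n_g$ the number of
genes the term annotates and $N_G$ the total number of annotated genes,
so broadly annotating (high-level) terms weigh less. Both weight families
are min–max normalized to $[0, 1]$, as are the GFIN's raw functional
interaction scores.

**Network (step 2).** The weighted term–gene–gene network (WTGGN) is an
undirected heterogeneous graph: term nodes joined to gene nodes by
normalized annotation weights, gene nodes joined by normalized
interaction weights. There are no term–term edges — terms communicate
only through genes. By default only genes present in the GFIN become gene
nodes (`geneMode = "intersection"`), because the walk needs gene–gene
connectivity; union mode exists for sensitivity analysis.

**Random walk (step 3).** A walker moves from node $u$ to neighbor $v$
with probability $d \cdot w(u,v) / \sum_k w(u,k)$ and dissipates with
probability $1 - d$ at every step; the damping $d$ defaults to 0.85, the
standard continuation probability of damped-walk models. Three
information-flow models are implemented as sparse linear systems
(`Matrix`), each solution certified by a relative-residual bound
(default $10^{-10}$):

* *emitting*: expected visits $v(u)$ to each non-sink node by a walker
  injected at a source, $v = e_{\mathrm{src}} + M^\top v$;
* *absorbing*: probability $a(u)$ that a walk from $u$ reaches a sink
  before dissipating, $a = M a + r$;
* *channel*: visits conditioned on eventual absorption at the sink,
  $h(u) = v(u)\, a(u) / a(\mathrm{src})$ — the Green's-function identity
  of the Doob transform, which our Monte-Carlo oracle verifies
  trajectory-by-trajectory in the test suite.

To represent a term, the term is both source and sink of a channel walk.
A literal source-equals-sink run is ill-defined, so the term node is
split: an emit-only source copy and an absorb-only sink copy both carry
the term's annotation edges; the walker leaves the source copy, wanders
the gene network, and is absorbed on returning to the sink copy or
dissipates. During a term's walk all *other* term nodes are removed
(genes are the transient nodes); keeping them as transient thoroughfares
is available as `termsTransient = TRUE` for sensitivity analysis. The
result is the term's vector of conditioned expected visits over all $N$
gene nodes.

**Similarity (step 4).**
$\mathrm{Sim}(t_i, t_j) = \cos(\theta)\, nw(t_i)\, nw(t_j)$: the cosine
of the two visit vectors, scaled by both normalized term weights to
counteract shallow annotation (high-level terms have diffuse, mutually
overlapping visit vectors; their small $nw$ compensates). Scores
therefore live in $[0, \min(nw_i, nw_j)] \subseteq [0, 1]$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `damping` | 0.85 | per-step continuation probability; larger values let flow explore farther from the term's own genes |
| `tolerance` | 1e-10 | relative residual the solver must certify |
| `geneMode` | intersection | gene nodes restricted to GFIN genes |
| `excludeEvidence` | IEA | GAF evidence codes dropped before weighting |
| `termWeightFloor` | 0 | optional lower clamp on $nw(t)$ |

Two deliberate edge-case rules: (i) degenerate min–max (all raw values
equal) maps every value to 1, so a uniformly weighted network keeps its
connectivity rather than vanishing; (ii) the single most-annotated term
receives $nw = 0$ and thus scores 0 against everything — faithful to the
formula; `termWeightFloor` documents the deviation if a user prefers an
epsilon floor. Zero-weight edges (the min–max minima) stay in the graph
structure but contribute no transition probability.

## Evaluation harness

Benchmarks follow the positive-group / negative-group protocol: a list
of known-similar cross-ontology pairs is the positive group; each
iteration samples `ratio` (default 10) times as many random pairs —
uniform without replacement over annotated-term pairs, positives
excluded — and the ranking is summarized by the ROC AUC, computed as the
tie-aware Mann–Whitney probability (equivalently the limit of
trapezoidal threshold-sweep integration). `iterateAUC()` reports the
mean, the population standard deviation (the benchmark's tiny SDs do not
disambiguate the n vs n−1 convention; population SD is used and
documented) and all per-iteration AUCs, reproducibly under a base seed.

`tfidfSimilarity()` quantifies a disease-by-phenotype occurrence-count
matrix with the simplest standard TF-IDF variant — tf is the raw count
and $\mathrm{idf}(j) = \log_2(N_{\mathrm{rows}} / \mathrm{df}(j))$,
base 2 for consistency with the weighting formulas — and
`pearsonCorrelation()` (a wrapper over `stats::cor.test`) compares score
vectors from independent evidence sources.

## What the synthetic generator emulates

`generateSynthetic()` produces, from a single seed, everything the
pipeline consumes, written in the real formats (OBO, GAF, 3-column TSV)
so the actual parsers are exercised:

* two rooted IS_A DAGs (non-root terms draw $1 + \mathrm{Pois}(b - 1)$
  parents among earlier terms; $b = 1.3$ mean parents per term, matching
  the mostly-tree-with-some-multiple-inheritance shape of curated
  ontologies);
* leaf-biased annotations, $\max(2, \mathrm{Pois}(6))$ genes per leaf
  term over a 150-gene pool (defaults), with curated-style evidence codes
  plus a sprinkle of IEA records for the filter to remove;
* a scale-free interaction network (preferential attachment, mean degree
  4) with log-normal(0, 1) interaction scores, giving the min–max
  normalization non-trivial spread;
* planted positive pairs, one term from each ontology, in two flavors:
  **shared** (the pair's equally-sized gene sets share a
  `plantedOverlap` fraction, default 0.8, of their genes — overlap 1
  means identical sets) and **adjacent** (disjoint gene sets, but the two
  sets are completely wired together in the interaction network). The
  adjacent mode is the discriminating case: the annotation-cosine
  baseline scores such pairs exactly 0, while the walk can follow the
  planted edges.

The default scale (30 + 30 terms, 150 genes, 8 planted pairs, ratio-10
negatives, 20 iterations) keeps a full benchmark under a few seconds on
one CPU while leaving enough terms for negative sampling; the test suite
and the acceptance script both run at this scale.

What the generator does *not* emulate: realistic GO/HumanNet topology
(term depths, annotation power laws, network modularity), identifier
mapping noise, taxon structure, or annotation bias. Passing benchmarks
here demonstrate that the implementation ranks planted signal above
chance under the model's own assumptions — not performance on real
corpora.

### Null calibration and its variance

With `plantedOverlap = 0` (and adjacency off) the "positives" are just
random leaf pairs and the mean AUC should sit near 0.5. Two caveats are
worth knowing. First, with only 8 positive pairs the per-benchmark AUC
has a sampling standard deviation near 0.1, so individual seeds can land
visibly off 0.5. Second, planted pairs are always leaf terms while
negative pairs are sampled from *all* annotated terms including
propagated internal ones; the term-weight correction compensates for the
cosine inflation of internal terms, but the cancellation is not exact on
every draw. The baseline cosine's null AUC sits well *below* 0.5 for the
same reason ties are credited one half: most leaf pairs share no genes
and score exactly 0, while occasional gene-sharing negatives score above
them.

## Numerical choices

* Linear systems are solved by a direct sparse factorization
  (`Matrix::solve`); for damping $< 1$ the operator is a strict
  contraction, so the systems are uniquely solvable and the residual
  check is a certificate, not a convergence heuristic.
* Isolated transient nodes (zero incident weight) get an all-zero
  transition row — pure dissipation, not an error; unreachable sinks
  yield an empty channel vector with a warning.
* All character sorting uses radix (C-locale) order, and scores are
  serialized at 6 significant digits, so identical inputs produce
  byte-identical outputs on any machine.
* Absorption probabilities are clamped to $[0, 1]$ after the solve to
  remove $10^{-16}$-scale excursions.

## Known limitations

* Gene identifiers are compared by exact string equality; callers must
  harmonize annotation and network namespaces beforehand.
* Only IS_A edges are honored (part_of and other relations are counted
  and ignored); the two input ontologies must have disjoint identifier
  sets and are treated as edge-disjoint DAGs.
* The term–gene weight depends on the gene only (its term count), so all
  edges of a given gene share a weight; this is the formula's stated
  form, not an implementation shortcut.
* All-pairs scoring solves two linear systems per term; on genome-scale
  networks (tens of thousands of genes) an iterative solver would be the
  natural extension and is not yet implemented.
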