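# infacront

Cross-ontology term similarity from information flow on a weighted
term–gene–gene network.

## What problem this solves

Biomedical ontologies (the Gene Ontology's BP/MF/CC sub-ontologies, the
Disease Ontology, the Human Phenotype Ontology, ...) each curate IS_A
relationships *within* themselves, but relationships *between* terms of
different ontologies are largely unmapped. Since most ontologies annotate
genes, a cross-ontology term pair can be compared through annotations.
Set-overlap methods (the vector-space model, VSM) treat genes as
independent and score zero whenever two terms annotate different —
even functionally coupled — genes. This package instead embeds both
ontologies' terms and a gene functional-interaction network (GFIN) in one
heterogeneous graph and lets a damped random walk carry information
between them, so network connectivity contributes to the score. It is
aimed at researchers linking terms across ontologies: disease–phenotype,
disease–process, or BP–MF term mapping.

## The method

1. **Weights.** Annotations (GAF, IEA evidence excluded, NOT-qualified
   records dropped) are propagated to IS_A ancestors. A term–gene pair is
   weighted `w(t_i, g_j) = -log2(n_j / N_T)` (`n_j` = terms annotating
   gene `g_j`, `N_T` = total annotation terms); a term is weighted
   `w(t_i) = -log2(n_g / N_G)` (`n_g` = genes annotated by the term,
   `N_G` = total annotated genes). Both families, and the GFIN's raw
   interaction scores, are min–max normalized to [0, 1].
2. **Network.** Terms connect to their annotated genes; genes connect by
   normalized interaction weights; no term–term edges.
3. **Walk.** A walker continues each step with damping `d = 0.85` and
   dissipates otherwise. The *channel* model — walks conditioned to
   leave a term and return to it — represents the term as the vector of
   conditioned expected visits `WV_t = (w_1, ..., w_N)` over all `N`
   gene nodes, solved as certified sparse linear systems (emitting
   visits × absorption probabilities, the Doob-transform identity).
4. **Score.** `Sim(t_i, t_j) = cos(WV_i, WV_j) · nw(t_i) · nw(t_j)`:
   the cosine of the visit vectors scaled by both normalized term
   weights, which counteract shallow annotation.

An evaluation harness (positive group vs repeatedly sampled random
negative groups, tie-aware Mann–Whitney AUC), a VSM baseline, TF-IDF
scoring of co-occurrence count matrices, Pearson comparison of score
vectors, and a seeded synthetic-data generator (OBO/GAF/TSV) are
included. See the vignette `vignettes/cross-ontology-similarity.Rmd` for
the full model description and design rationale.

## Worked example

```r
library(infacront)

# A seeded synthetic benchmark: two 30-term ontologies, 150 genes,
# 8 planted similar pairs, written as real OBO/GAF/TSV files.
fx <- generateSynthetic(syntheticSpec(seed = 42))
fx$ontologyA
#> Ontology with 30 terms, 42 IS_A edges, 1 root(s)

# Full pipeline: parse, filter IEA, propagate, weight, assemble, walk, score.
tab <- crossOntologySimilarity(fx$files[["oboA"]], fx$files[["oboB"]],
                               fx$files[["gaf"]], fx$files[["gfin"]])
attr(tab, "graph")
#> WTGGN: 60 term nodes, 93 gene nodes, 854 term-gene edges, 118 gene-gene edges

head(tab[order(-tab$score), ], 5)
#>           term_a       term_b    method     score
#> 772 SYNA:0000026 SYNB:0000022 infacront 0.3771443
#> 557 SYNA:0000019 SYNB:0000017 infacront 0.3405476
#> 559 SYNA:0000019 SYNB:0000019 infacront 0.3405476
#> 570 SYNA:0000019 SYNB:0000030 infacront 0.3405476
#> 478 SYNA:0000016 SYNB:0000028 infacront 0.2743988
```

Scores are the weight-adjusted cosine: a value like 0.38 means the two
terms' walk vectors point in similar directions *and* both terms are
specific (high normalized weight); broad terms are damped toward 0. Six
of the eight planted pairs land in the top eight scores here. The
benchmark harness quantifies this:

```r
res <- benchmarkAUC(fx, iterations = 20, baseSeed = 42)
sprintf("infacront mean AUC %.4f (SD %.4f); vsm mean AUC %.4f",
        res$infacront$mean, res$infacront$sd, res$vsm$mean)
#> "infacront mean AUC 0.9960 (SD 0.0047); vsm mean AUC 0.9968"
```

With shared-gene planted pairs both methods separate well. The
discriminating case is `syntheticSpec(plantedMode = "adjacent")`, where
planted pairs share *no* genes but their gene sets are wired together in
the interaction network: VSM scores those pairs exactly 0 while the walk
still ranks them highly.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/infacront.R similarity \
    --obo-a a.obo --obo-b b.obo --gaf ann.gaf --gfin net.tsv --out sims.tsv
Rscript inst/scripts/infacront.R simulate --spec spec.json --out-dir fixtures/
```

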