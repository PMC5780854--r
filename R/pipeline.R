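#' End-to-end cross-ontology similarity pipeline
#'
#' Runs the full method from files on disk: parses the two OBO ontologies
#' and the GAF annotations (filtering the excluded evidence codes),
#' propagates annotations to IS_A ancestors, computes the
#' information-theoretic term-gene and term weights (pooled min-max
#' normalization), normalizes the functional-interaction scores, assembles
#' the weighted term-gene-gene network, and scores every cross-ontology
#' pair of annotated terms with the channel-walk similarity. Terms of the
#' two ontologies must have disjoint identifier sets.
#'
#' @param oboA,oboB paths to the two OBO ontology files.
#' @param gaf path to the GAF annotation file covering both ontologies.
#' @param gfin path to the 3-column gene interaction edge list.
#' @param excludeEvidence evidence codes to drop (default `"IEA"`).
#' @param propagate propagate annotations to ancestors before weighting.
#' @param geneMode gene-node policy of [buildWTGGN()].
#' @param config a [WalkConfig-class].
#' @param output optional path; when given the similarity table is also
#'   written there as TSV (byte-identical across reruns).
#' @return the similarity table of [allPairsSimilarity()], with attribute
#'   `"graph"` carrying the assembled [WTGGN-class].
#' @export
crossOntologySimilarity <- function(oboA, oboB, gaf, gfin,
                                    excludeEvidence = "IEA",
                                    propagate = TRUE,
                                    geneMode = c("intersection", "union"),
                                    config = walkConfig(),
                                    output = NULL) {
  geneMode <- match.arg(geneMode)
  ontA <- parseOBO(oboA)
  ontB <- parseOBO(oboB)
  if (length(intersect(terms(ontA), terms(ontB))))
    .stopf("the two ontologies share term identifiers; inputs must be disjoint")
  ann <- parseGAF(gaf, excludeEvidence = excludeEvidence,
                  ontology = list(ontA, ontB))
  if (propagate) ann <- propagateAnnotations(ann, list(ontA, ontB))
  wt <- computeWeights(ann)
  net <- buildWTGGN(ann, wt, normalizeGFIN(readGFIN(gfin)),
                    geneMode = geneMode)
  annotated <- terms(ann)
  tab <- allPairsSimilarity(net,
                            intersect(annotated, terms(ontA)),
                            intersect(annotated, terms(ontB)),
                            config = config)
  if (!is.null(output)) writeSimilarityTable(tab, output)
  attr(tab, "graph") <- net
  tab
}
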