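#' Term identifiers of an object
#'
#' @param x an [Ontology-class], [AnnotationSet-class] or [WTGGN-class].
#' @param ... ignored.
#' @return character vector of term identifiers.
#' @export
setGeneric("terms")

#' Ancestors of a term
#'
#' All terms reachable from `term` by following IS_A edges upward
#' (transitively), excluding the term itself. The result for a root term is
#' the empty set.
#'
#' @param ontology an [Ontology-class].
#' @param term a term identifier present in the ontology.
#' @return character vector of ancestor term identifiers (unordered set).
#' @export
setGeneric("ancestors", function(ontology, term) standardGeneric("ancestors"))

#' Root terms of an ontology
#'
#' Terms with no outgoing IS_A edge.
#'
#' @param ontology an [Ontology-class].
#' @return character vector of root term identifiers.
#' @export
setGeneric("roots", function(ontology) standardGeneric("roots"))

#' IS_A edges of an ontology
#'
#' @param ontology an [Ontology-class].
#' @return data.frame with columns `child`, `parent`.
#' @export
setGeneric("isaEdges", function(ontology) standardGeneric("isaEdges"))

#' Unique (term, gene) annotation pairs
#'
#' @param x an [AnnotationSet-class].
#' @return data.frame with columns `term`, `gene`, one row per unique pair.
#' @export
setGeneric("annotationPairs", function(x) standardGeneric("annotationPairs"))

#' Annotated genes
#'
#' @param x an [AnnotationSet-class] or [WTGGN-class].
#' @return character vector of gene identifiers.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Number of annotation terms per gene (n_j)
#'
#' @param x an [AnnotationSet-class].
#' @return named integer vector: for each gene, the number of distinct terms
#'   annotating it.
#' @export
setGeneric("nTermsPerGene", function(x) standardGeneric("nTermsPerGene"))

#' Number of annotated genes per term (n_g)
#'
#' @param x an [AnnotationSet-class].
#' @return named integer vector: for each term, the number of distinct genes
#'   it annotates.
#' @export
setGeneric("nGenesPerTerm", function(x) standardGeneric("nGenesPerTerm"))

#' Normalized term weights nw(t) of a network
#'
#' @param x a [WTGGN-class].
#' @return named numeric vector in [0, 1].
#' @export
setGeneric("termNormWeights", function(x) standardGeneric("termNormWeights"))

#' Visit weights of a term vector
#'
#' @param x a [TermVector-class].
#' @return named non-negative numeric vector over gene nodes.
#' @export
setGeneric("visitWeights", function(x) standardGeneric("visitWeights"))
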