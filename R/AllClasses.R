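#' @import methods
#' @importFrom stats cor cor.test rlnorm rpois runif setNames
#' @importFrom utils read.table write.table head
NULL

#' Ontology: an IS_A directed acyclic graph of terms
#'
#' Container for one ontology parsed from an OBO file. Terms are nodes of a
#' DAG whose directed edges point from a child term to its IS_A parent.
#' Only IS_A edges are stored; obsolete terms are dropped at parse time and
#' alternative identifiers are kept as a map onto their primary identifier.
#'
#' @slot terms character vector of non-obsolete term identifiers.
#' @slot termNames named character vector of human-readable term names.
#' @slot termNamespace named character vector of per-term namespace labels
#'   (may be empty strings).
#' @slot edges data.frame with columns `child`, `parent`: one row per IS_A
#'   relationship, both endpoints declared non-obsolete terms.
#' @slot altIds named character vector mapping alternative ids to primary ids.
#' @slot source character scalar; origin of the ontology (file path or label).
#'
#' @seealso [parseOBO()], [ancestors()], [roots()]
#' @export
setClass("Ontology",
  representation(
    terms = "character",
    termNames = "character",
    termNamespace = "character",
    edges = "data.frame",
    altIds = "character",
    source = "character"
  ),
  prototype(
    terms = character(),
    termNames = character(),
    termNamespace = character(),
    edges = data.frame(child = character(), parent = character(),
                       stringsAsFactors = FALSE),
    altIds = character(),
    source = NA_character_
  )
)

setValidity("Ontology", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("child", "parent") %in% colnames(ed)))
    msg <- c(msg, "edges must have columns 'child' and 'parent'")
  else {
    bad <- !(ed$child %in% object@terms) | !(ed$parent %in% object@terms)
    if (any(bad))
      msg <- c(msg, sprintf("%d IS_A edge(s) reference undeclared terms",
                            sum(bad)))
    if (nrow(ed) > 0L && any(ed$child == ed$parent))
      msg <- c(msg, "self IS_A edges are not allowed")
    cyc <- .findCycle(object@terms, ed)
    if (!is.null(cyc))
      msg <- c(msg, paste0("IS_A graph contains a cycle: ",
                           paste(cyc, collapse = " -> ")))
  }
  if (anyDuplicated(object@terms))
    msg <- c(msg, "duplicated term identifiers")
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: deduplicated term-gene annotation records
#'
#' Holds term-gene annotation records (with their evidence codes) parsed
#' from a GAF file or produced by ancestor propagation. Records are unique
#' as (term, gene, evidence) triples; all incidence counts are computed over
#' the unique (term, gene) pairs.
#'
#' @slot records data.frame with columns `term`, `gene`, `evidence`.
#'
#' @seealso [parseGAF()], [propagateAnnotations()], [annotationPairs()]
#' @export
setClass("AnnotationSet",
  representation(records = "data.frame"),
  prototype(records = data.frame(term = character(), gene = character(),
                                 evidence = character(),
                                 stringsAsFactors = FALSE))
)

setValidity("AnnotationSet", function(object) {
  rec <- object@records
  if (!all(c("term", "gene", "evidence") %in% colnames(rec)))
    return("records must have columns 'term', 'gene', 'evidence'")
  if (anyDuplicated(rec[, c("term", "gene", "evidence")]))
    return("duplicated (term, gene, evidence) records")
  TRUE
})

#' WeightTable: information-theoretic term-gene and term weights
#'
#' Raw weights are in bits: a term-gene pair weighs -log2(n_j / N_T), where
#' n_j is the number of terms annotating gene g_j and N_T the total number
#' of annotation terms; a term weighs -log2(n_g / N_G), where n_g is the
#' number of genes it annotates and N_G the total number of annotated genes.
#' Both sets of raw weights are min-max normalized to the unit interval.
#'
#' @slot termGene data.frame with columns `term`, `gene`, `raw`, `norm`.
#' @slot term data.frame with columns `term`, `raw`, `norm`.
#'
#' @seealso [computeWeights()], [termGeneWeight()], [termWeight()]
#' @export
setClass("WeightTable",
  representation(termGene = "data.frame", term = "data.frame")
)

setValidity("WeightTable", function(object) {
  msg <- character()
  tg <- object@termGene; tw <- object@term
  if (!all(c("term", "gene", "raw", "norm") %in% colnames(tg)))
    msg <- c(msg, "termGene must have columns term, gene, raw, norm")
  if (!all(c("term", "raw", "norm") %in% colnames(tw)))
    msg <- c(msg, "term must have columns term, raw, norm")
  if (!length(msg)) {
    if (any(tg$raw < 0) || any(tw$raw < 0))
      msg <- c(msg, "raw weights must be non-negative")
    if (any(tg$norm < -1e-12 | tg$norm > 1 + 1e-12) ||
        any(tw$norm < -1e-12 | tw$norm > 1 + 1e-12))
      msg <- c(msg, "normalized weights must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' WTGGN: weighted term-gene-gene network
#'
#' Heterogeneous undirected graph with two node types (terms, genes) and two
#' edge types: term-gene edges carry normalized annotation weights, and
#' gene-gene edges carry min-max normalized functional-interaction scores.
#' There are no term-term edges and no self loops. Every term node has at
#' least one incident term-gene edge; terms losing all their genes during
#' assembly are dropped and recorded in `dropped`.
#'
#' @slot termNodes character vector of term node identifiers.
#' @slot geneNodes character vector of gene node identifiers.
#' @slot tgEdges data.frame with columns `term`, `gene`, `weight` in [0,1].
#' @slot ggEdges data.frame with columns `gene1`, `gene2`, `weight` in [0,1];
#'   each undirected edge stored once with `gene1 < gene2`.
#' @slot termWeights named numeric; normalized term weight nw(t) per term node.
#' @slot dropped character vector of terms dropped during assembly.
#'
#' @seealso [buildWTGGN()], [termVector()], [allPairsSimilarity()]
#' @export
setClass("WTGGN",
  representation(
    termNodes = "character",
    geneNodes = "character",
    tgEdges = "data.frame",
    ggEdges = "data.frame",
    termWeights = "numeric",
    dropped = "character"
  )
)

setValidity("WTGGN", function(object) {
  msg <- character()
  tg <- object@tgEdges; gg <- object@ggEdges
  if (!all(c("term", "gene", "weight") %in% colnames(tg)))
    msg <- c(msg, "tgEdges must have columns term, gene, weight")
  if (!all(c("gene1", "gene2", "weight") %in% colnames(gg)))
    msg <- c(msg, "ggEdges must have columns gene1, gene2, weight")
  if (length(msg)) return(msg)
  if (length(intersect(object@termNodes, object@geneNodes)))
    msg <- c(msg, "term and gene node identifiers must be disjoint")
  if (!all(tg$term %in% object@termNodes) ||
      !all(tg$gene %in% object@geneNodes))
    msg <- c(msg, "term-gene edge endpoints must be declared nodes")
  if (nrow(gg) > 0L) {
    if (!all(gg$gene1 %in% object@geneNodes) ||
        !all(gg$gene2 %in% object@geneNodes))
      msg <- c(msg, "gene-gene edge endpoints must be declared gene nodes")
    if (any(gg$gene1 == gg$gene2))
      msg <- c(msg, "self loops are not allowed")
    if (any(gg$gene1 >= gg$gene2))
      msg <- c(msg, "gene-gene edges must be stored once with gene1 < gene2")
  }
  if (any(tg$weight < 0 | tg$weight > 1) ||
      (nrow(gg) > 0L && any(gg$weight < 0 | gg$weight > 1)))
    msg <- c(msg, "edge weights must lie in [0, 1]")
  if (!all(object@termNodes %in% tg$term))
    msg <- c(msg, "every term node needs at least one term-gene edge")
  if (!all(object@termNodes %in% names(object@termWeights)))
    msg <- c(msg, "termWeights must cover every term node")
  if (length(msg)) msg else TRUE
})

#' WalkConfig: parameters of the damped random walk
#'
#' @slot damping per-step continuation probability in (0, 1); the walker
#'   dissipates with probability 1 - damping at every step. Default 0.85.
#' @slot tolerance relative residual bound certified by the linear solver.
#' @slot model which information-flow model a driver should run; one of
#'   "channel", "emitting", "absorbing".
#'
#' @seealso [walkConfig()]
#' @export
setClass("WalkConfig",
  representation(damping = "numeric", tolerance = "numeric",
                 model = "character")
)

setValidity("WalkConfig", function(object) {
  msg <- character()
  if (length(object@damping) != 1L || !is.finite(object@damping) ||
      object@damping <= 0 || object@damping >= 1)
    msg <- c(msg, "damping must be a single number in (0, 1)")
  if (length(object@tolerance) != 1L || object@tolerance <= 0)
    msg <- c(msg, "tolerance must be a single positive number")
  if (length(object@model) != 1L ||
      !object@model %in% c("channel", "emitting", "absorbing"))
    msg <- c(msg, "model must be one of 'channel', 'emitting', 'absorbing'")
  if (length(msg)) msg else TRUE
})

#' TermVector: per-gene visit weights representing one term
#'
#' The N-dimensional representation of a term obtained from the channel
#' random walk: entry n is the expected number of visits to gene n by a
#' damped walker that leaves the term and is conditioned to return to it.
#' Genes never visited (including genes unreachable from the term) have
#' weight 0.
#'
#' @slot term the term identifier.
#' @slot weights named non-negative numeric vector over all gene nodes of
#'   the network the vector was computed on.
#'
#' @seealso [termVector()], [visitWeights()]
#' @export
setClass("TermVector",
  representation(term = "character", weights = "numeric")
)

setValidity("TermVector", function(object) {
  msg <- character()
  if (length(object@term) != 1L)
    msg <- c(msg, "term must be a single identifier")
  w <- object@weights
  if (is.null(names(w)) && length(w) > 0L)
    msg <- c(msg, "weights must be named by gene")
  if (any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  if (length(msg)) msg else TRUE
})
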