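#' Cosine of two non-negative vectors
#'
#' @param u,v numeric non-negative vectors of the same length, each with at
#'   least one nonzero entry.
#' @return cosine similarity in [0, 1] (for non-negative inputs).
#' @examples
#' cosineSimilarity(c(1, 2, 0), c(2, 1, 0))  # 0.8
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) .stopf("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) .stopf("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Weight-adjusted cosine similarity between two term vectors
#'
#' The cross-ontology similarity score: the cosine of the two gene
#' visit-weight vectors multiplied by both normalized term weights,
#' `Sim(t_i, t_j) = cos(theta) * nw(t_i) * nw(t_j)`. The term-weight
#' factors penalize shallowly annotating (high-level) terms whose vectors
#' would otherwise overlap with everything.
#'
#' @param va,vb [TermVector-class] objects (or plain named numeric vectors)
#'   over the same gene universe.
#' @param nwA,nwB normalized term weights in [0, 1].
#' @return similarity score in [0, min(nwA, nwB)].
#' @export
infacrontSimilarity <- function(va, vb, nwA, nwB) {
  ua <- if (is(va, "TermVector")) va@weights else va
  ub <- if (is(vb, "TermVector")) vb@weights else vb
  cosineSimilarity(ua, ub) * nwA * nwB
}

#' Vector-space-model baseline similarity
#'
#' The cosine of the two terms' binary gene-incidence vectors, which for
#' sets reduces to `|G_a intersect G_b| / sqrt(|G_a| * |G_b|)`. Ignores
#' the interaction network entirely.
#'
#' @param annotations an [AnnotationSet-class].
#' @param termA,termB term identifiers with at least one annotated gene.
#' @return similarity in [0, 1].
#' @export
vsmSimilarity <- function(annotations, termA, termB) {
  p <- annotationPairs(annotations)
  ga <- p$gene[p$term == termA]
  gb <- p$gene[p$term == termB]
  if (!length(ga)) .stopf("term '%s' has no annotated genes", termA)
  if (!length(gb)) .stopf("term '%s' has no annotated genes", termB)
  length(intersect(ga, gb)) / sqrt(length(ga) * length(gb))
}

#' All cross-ontology pair similarities
#'
#' Computes each term's channel-walk vector once (cached), then scores
#' every cross-ontology term pair with the weight-adjusted cosine. Terms
#' missing from the graph are skipped and reported; terms whose vector is
#' identically zero (their genes are unreachable or all their edge weights
#' are zero) score 0 against everything, with a warning. Output ordering
#' is lexicographic by pair, so reruns are byte-identical.
#'
#' @param graph a [WTGGN-class].
#' @param termsA,termsB disjoint character vectors of term ids from the two
#'   ontologies.
#' @param config a [WalkConfig-class].
#' @param includeIntra also score within-ontology pairs.
#' @return a similarity table: data.frame with columns `term_a`, `term_b`,
#'   `method` (`"infacront"`), `score`, plus attribute `"skipped"` listing
#'   terms absent from the graph.
#' @export
allPairsSimilarity <- function(graph, termsA, termsB, config = walkConfig(),
                               includeIntra = FALSE) {
  stopifnot(is(graph, "WTGGN"))
  if (length(intersect(termsA, termsB)))
    .stopf("termsA and termsB must be disjoint")
  skipped <- .sortC(setdiff(c(termsA, termsB), graph@termNodes))
  if (length(skipped))
    message(sprintf("skipping %d term(s) absent from the network",
                    length(skipped)))
  termsA <- .sortC(intersect(termsA, graph@termNodes))
  termsB <- .sortC(intersect(termsB, graph@termNodes))
  vecs <- .termVectorCache(graph, c(termsA, termsB), config)
  nw <- graph@termWeights

  pairsAB <- expand.grid(term_a = termsA, term_b = termsB,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (includeIntra) {
    intra <- function(ts) {
      if (length(ts) < 2L) return(NULL)
      cmb <- utils::combn(ts, 2L)
      .df(term_a = cmb[1L, ], term_b = cmb[2L, ])
    }
    pairsAB <- rbind(pairsAB, intra(termsA), intra(termsB))
  }
  pairsAB <- pairsAB[.orderC(pairsAB$term_a, pairsAB$term_b), , drop = FALSE]

  zeroSeen <- FALSE
  score <- mapply(function(a, b) {
    ua <- vecs[[a]]; ub <- vecs[[b]]
    if (sum(ua) == 0 || sum(ub) == 0) {
      zeroSeen <<- TRUE
      return(0)
    }
    cosineSimilarity(ua, ub) * nw[[a]] * nw[[b]]
  }, pairsAB$term_a, pairsAB$term_b, USE.NAMES = FALSE)
  if (zeroSeen)
    .warnf("one or more terms have zero visit vectors; their pairs score 0")

  out <- .df(term_a = pairsAB$term_a, term_b = pairsAB$term_b,
             method = "infacront", score = score)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

.termVectorCache <- function(graph, termIds, config) {
  vecs <- vector("list", length(termIds))
  names(vecs) <- termIds
  for (t in termIds)
    vecs[[t]] <- suppressWarnings(termVector(graph, t, config))@weights
  vecs
}

#' Score arbitrary term pairs with the channel-walk similarity
#'
#' Returns a scoring closure over a network: given a data.frame of pairs
#' (columns `term_a`, `term_b`) it returns their weight-adjusted cosine
#' scores, computing and caching term vectors on demand. Pairs involving
#' terms absent from the graph, or terms with zero visit vectors, score 0.
#'
#' @param graph a [WTGGN-class].
#' @param config a [WalkConfig-class].
#' @return function(pairs) -> numeric scores.
#' @export
infacrontScorer <- function(graph, config = walkConfig()) {
  stopifnot(is(graph, "WTGGN"))
  cache <- new.env(parent = emptyenv())
  nw <- graph@termWeights
  getVec <- function(t) {
    if (!t %in% graph@termNodes) return(NULL)
    if (is.null(cache[[t]]))
      cache[[t]] <- suppressWarnings(termVector(graph, t, config))@weights
    cache[[t]]
  }
  function(pairs) {
    mapply(function(a, b) {
      ua <- getVec(a); ub <- getVec(b)
      if (is.null(ua) || is.null(ub) || sum(ua) == 0 || sum(ub) == 0)
        return(0)
      cosineSimilarity(ua, ub) * nw[[a]] * nw[[b]]
    }, pairs$term_a, pairs$term_b, USE.NAMES = FALSE)
  }
}

#' Score term pairs with the vector-space-model baseline
#'
#' @param annotations an [AnnotationSet-class].
#' @return function(pairs) -> numeric scores; pairs with an unannotated
#'   term score 0.
#' @export
vsmScorer <- function(annotations) {
  p <- annotationPairs(annotations)
  geneSets <- split(p$gene, p$term)
  function(pairs) {
    mapply(function(a, b) {
      ga <- geneSets[[a]]; gb <- geneSets[[b]]
      if (is.null(ga) || is.null(gb)) return(0)
      length(intersect(ga, gb)) / sqrt(length(ga) * length(gb))
    }, pairs$term_a, pairs$term_b, USE.NAMES = FALSE)
  }
}

#' Write a similarity table to TSV
#'
#' Scores are written with 6 significant digits; rerunning the pipeline on
#' identical inputs produces a byte-identical file.
#'
#' @param table data.frame with columns `term_a`, `term_b`, `method`,
#'   `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimilarityTable <- function(table, path) {
  df <- .df(term_a = table$term_a, term_b = table$term_b,
            method = table$method, score = sprintf("%.6g", table$score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
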