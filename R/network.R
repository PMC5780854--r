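#' Assemble the weighted term-gene-gene network
#'
#' Combines the normalized term-gene weights with the normalized gene
#' functional-interaction network into a single undirected heterogeneous
#' graph. With `geneMode = "intersection"` (default) only genes present in
#' the GFIN become gene nodes — the random walk needs gene-gene
#' connectivity; with `geneMode = "union"` annotated genes absent from the
#' GFIN are kept as gene nodes carrying only term edges. Terms left with no
#' surviving term-gene edge are dropped and reported (and listed in the
#' `dropped` slot).
#'
#' @param annotations an [AnnotationSet-class] (the one `weights` was
#'   computed on).
#' @param weights a [WeightTable-class] from [computeWeights()].
#' @param gfin normalized gene-gene edge list from [normalizeGFIN()]
#'   (columns `gene1`, `gene2`, `weight`).
#' @param geneMode `"intersection"` or `"union"`.
#' @return a [WTGGN-class].
#' @export
buildWTGGN <- function(annotations, weights, gfin,
                       geneMode = c("intersection", "union")) {
  geneMode <- match.arg(geneMode)
  stopifnot(is(annotations, "AnnotationSet"), is(weights, "WeightTable"))
  stopifnot(all(c("gene1", "gene2", "weight") %in% colnames(gfin)))

  tg <- weights@termGene
  gfinGenes <- unique(c(gfin$gene1, gfin$gene2))
  annotGenes <- unique(tg$gene)

  geneNodes <- if (geneMode == "intersection") {
    intersect(annotGenes, gfinGenes)
  } else {
    union(annotGenes, gfinGenes)
  }
  tgKeep <- tg[tg$gene %in% geneNodes, c("term", "gene", "norm")]
  colnames(tgKeep)[3L] <- "weight"

  allTerms <- unique(tg$term)
  survivors <- unique(tgKeep$term)
  dropped <- setdiff(allTerms, survivors)
  if (length(dropped))
    message(sprintf("dropped %d term(s) with no surviving gene edge: %s",
                    length(dropped),
                    paste(head(.sortC(dropped), 5L), collapse = ", ")))
  if (nrow(tgKeep) == 0L) .stopf("empty network: no term-gene edge survives")

  gg <- gfin[gfin$gene1 %in% geneNodes & gfin$gene2 %in% geneNodes,
             c("gene1", "gene2", "weight")]

  tw <- weights@term
  termW <- setNames(tw$norm, tw$term)[survivors]

  tgKeep <- tgKeep[.orderC(tgKeep$term, tgKeep$gene), , drop = FALSE]
  gg <- gg[.orderC(gg$gene1, gg$gene2), , drop = FALSE]
  rownames(tgKeep) <- rownames(gg) <- NULL
  new("WTGGN",
      termNodes = .sortC(survivors),
      geneNodes = .sortC(geneNodes),
      tgEdges = tgKeep, ggEdges = gg,
      termWeights = termW, dropped = .sortC(dropped))
}

#' @describeIn buildWTGGN term nodes of the network.
#' @param x a [WTGGN-class].
#' @param ... ignored.
#' @export
setMethod("terms", "WTGGN", function(x, ...) x@termNodes)

#' @rdname genes
#' @export
setMethod("genes", "WTGGN", function(x) x@geneNodes)

#' @rdname termNormWeights
#' @export
setMethod("termNormWeights", "WTGGN", function(x) x@termWeights)

#' @export
setMethod("show", "WTGGN", function(object) {
  cat(sprintf(
    "WTGGN: %d term nodes, %d gene nodes, %d term-gene edges, %d gene-gene edges\n",
    length(object@termNodes), length(object@geneNodes),
    nrow(object@tgEdges), nrow(object@ggEdges)))
  if (length(object@dropped))
    cat(sprintf("  %d term(s) dropped during assembly\n",
                length(object@dropped)))
})

#' Serialize a network to an edge-list TSV
#'
#' Columns: node1, node2, weight, edge_type (`TG` for term-gene, `GG` for
#' gene-gene). Weights are written with full precision (`%.17g`) so a
#' round trip through [readEdgeList()] reproduces them bit for bit.
#'
#' @param graph a [WTGGN-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "WTGGN"))
  tg <- graph@tgEdges; gg <- graph@ggEdges
  df <- .df(
    node1 = c(tg$term, gg$gene1),
    node2 = c(tg$gene, gg$gene2),
    weight = sprintf("%.17g", c(tg$weight, gg$weight)),
    edge_type = c(rep("TG", nrow(tg)), rep("GG", nrow(gg)))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [writeEdgeList()]
#'
#' @param path path to the TSV.
#' @return data.frame with columns `node1`, `node2`, `weight`, `edge_type`.
#' @export
readEdgeList <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric",
                                  "character"))
  if (!all(df$edge_type %in% c("TG", "GG")))
    .stopf("unknown edge_type values in %s", path)
  df
}
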