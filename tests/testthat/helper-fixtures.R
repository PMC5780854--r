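# Small fixtures built in code: OBO/GAF text writers, toy graphs and
# networks shared across test files.

writeTempOBO <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

# OBO text for a named edge list: terms is a character vector,
# edges a data.frame(child, parent).
oboText <- function(terms, edges, names = NULL, extra = list()) {
  out <- character()
  for (t in terms) {
    block <- c("[Term]", paste0("id: ", t))
    if (!is.null(names) && t %in% names(names))
      block <- c(block, paste0("name: ", names[[t]]))
    ps <- edges$parent[edges$child == t]
    if (length(ps)) block <- c(block, paste0("is_a: ", ps))
    if (t %in% names(extra)) block <- c(block, extra[[t]])
    out <- c(out, block, "")
  }
  out
}

# GAF text: records is a data.frame(gene, term, evidence, qualifier?).
gafText <- function(records) {
  if (is.null(records$qualifier)) records$qualifier <- ""
  lines <- sprintf(
    "DB\t%s\t%s\t%s\t%s\tREF:1\t%s\t\tP\t\t\tgene\ttaxon:1\t20260101\tDB\t\t",
    records$gene, records$gene, records$qualifier, records$term,
    records$evidence)
  c("!gaf-version: 2.1", lines)
}

writeTempGAF <- function(records) {
  path <- tempfile(fileext = ".gaf")
  writeLines(gafText(records), path)
  path
}

# Symmetric weight matrix from an edge list matrix cbind(from, to, weight).
symMatrix <- function(nodes, edges) {
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    w <- as.numeric(edges[k, 3L])
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  W
}

pathABC <- function() {
  symMatrix(c("A", "B", "C"), rbind(c("A", "B", 1), c("B", "C", 1)))
}

# A small hand-assembled WTGGN: two terms, four genes.
#   t1 - g1 (0.9), t1 - g2 (0.6); t2 - g3 (0.8), t2 - g4 (0.5)
#   g1 - g3 (0.7), g2 - g3 (0.4), g3 - g4 (1.0), g1 - g2 (0.2)
toyWTGGN <- function() {
  new("WTGGN",
      termNodes = c("t1", "t2"),
      geneNodes = c("g1", "g2", "g3", "g4"),
      tgEdges = data.frame(
        term = c("t1", "t1", "t2", "t2"),
        gene = c("g1", "g2", "g3", "g4"),
        weight = c(0.9, 0.6, 0.8, 0.5),
        stringsAsFactors = FALSE),
      ggEdges = data.frame(
        gene1 = c("g1", "g2", "g3", "g1"),
        gene2 = c("g3", "g3", "g4", "g2"),
        weight = c(0.7, 0.4, 1.0, 0.2),
        stringsAsFactors = FALSE),
      termWeights = c(t1 = 0.75, t2 = 0.5),
      dropped = character())
}

# The directed split-graph for a focal term of a WTGGN, built by hand
# (independently of the package's internal construction): the source copy
# "SRC" carries the term's annotation edges outgoing-only, the term node
# keeps them incoming-only, other terms are absent.
splitWalkMatrix <- function(wtggn, term) {
  tg <- wtggn@tgEdges[wtggn@tgEdges$term == term, ]
  gg <- wtggn@ggEdges
  nodes <- c(wtggn@geneNodes, term, "SRC")
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(gg))) {
    W[gg$gene1[k], gg$gene2[k]] <- gg$weight[k]
    W[gg$gene2[k], gg$gene1[k]] <- gg$weight[k]
  }
  for (k in seq_len(nrow(tg))) {
    W["SRC", tg$gene[k]] <- tg$weight[k]
    W[tg$gene[k], term] <- tg$weight[k]
  }
  W
}

# Random connected undirected weighted graph on <= 12 nodes.
randomFixtureGraph <- function(seed, nNodes = NULL) {
  set.seed(seed)
  if (is.null(nNodes)) nNodes <- sample(5:12, 1L)
  repeat {
    g <- igraph::sample_gnp(nNodes, p = 0.4)
    if (igraph::is_connected(g)) break
  }
  nodes <- sprintf("n%02d", seq_len(nNodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  W <- matrix(0, nNodes, nNodes, dimnames = list(nodes, nodes))
  w <- runif(nrow(el), 0.5, 1.5)
  for (k in seq_len(nrow(el))) {
    W[el[k, 1L], el[k, 2L]] <- w[k]
    W[el[k, 2L], el[k, 1L]] <- w[k]
  }
  W
}
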