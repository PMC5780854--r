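#' Random-walk configuration
#'
#' @param damping per-step continuation probability; the walker dissipates
#'   with probability `1 - damping` at every step. Default 0.85 (the
#'   PageRank convention).
#' @param tolerance relative residual bound the linear solver must certify.
#' @param model information-flow model for drivers that take one.
#' @return a [WalkConfig-class].
#' @export
walkConfig <- function(damping = 0.85, tolerance = 1e-10,
                       model = c("channel", "emitting", "absorbing")) {
  new("WalkConfig", damping = damping, tolerance = tolerance,
      model = match.arg(model))
}

#' @export
setMethod("show", "WalkConfig", function(object) {
  cat(sprintf("WalkConfig: model=%s damping=%g tolerance=%g\n",
              object@model, object@damping, object@tolerance))
})

# Coerce a walkable graph to a directed sparse weight matrix with dimnames.
# WTGGN edges are undirected, so both orientations are materialized.
.walkMatrix <- function(graph) {
  if (is(graph, "WTGGN")) {
    nodes <- c(graph@termNodes, graph@geneNodes)
    idx <- setNames(seq_along(nodes), nodes)
    tg <- graph@tgEdges; gg <- graph@ggEdges
    i <- c(idx[tg$term], idx[tg$gene], idx[gg$gene1], idx[gg$gene2])
    j <- c(idx[tg$gene], idx[tg$term], idx[gg$gene2], idx[gg$gene1])
    w <- c(tg$weight, tg$weight, gg$weight, gg$weight)
    W <- Matrix::sparseMatrix(i = i, j = j, x = w,
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
    return(W)
  }
  W <- as(Matrix::Matrix(graph, sparse = TRUE), "generalMatrix")
  if (nrow(W) != ncol(W) || is.null(rownames(W)) ||
      !identical(rownames(W), colnames(W)))
    .stopf("walk graph matrix must be square with matching dimnames")
  if (any(W@x < 0)) .stopf("negative edge weights are not allowed")
  W
}

# Damped transition pieces for a set of absorbing nodes.
# M: transient x transient move probabilities; R: transient x sinks;
# dieNow: transient nodes with zero total incident weight (pure dissipation).
.walkSystem <- function(W, sinks, damping) {
  nodes <- rownames(W)
  if (!all(sinks %in% nodes))
    .stopf("unknown sink node(s): %s",
           paste(setdiff(sinks, nodes), collapse = ", "))
  transient <- setdiff(nodes, sinks)
  if (!length(transient)) .stopf("no transient nodes")
  rowTot <- Matrix::rowSums(W)
  scale <- ifelse(rowTot[transient] > 0, damping / rowTot[transient], 0)
  P <- Matrix::Diagonal(x = scale) %*% W[transient, , drop = FALSE]
  dimnames(P) <- list(transient, nodes)
  list(
    M = P[, transient, drop = FALSE],
    R = P[, sinks, drop = FALSE],
    transient = transient,
    rowTot = rowTot
  )
}

.solveCertified <- function(A, b, tolerance, what) {
  x <- as.numeric(Matrix::solve(A, b))
  res <- sqrt(sum(as.numeric(A %*% x - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (!is.finite(res) || res > tolerance)
    .stopf("%s solve did not certify: relative residual %.3e > %.3e",
           what, res, tolerance)
  x
}

#' Damped transition matrix over transient nodes
#'
#' For a transient node u, the probability of moving to node v is
#' `damping * w(u, v) / sum_k w(u, k)`, with the denominator summing edge
#' weights over all neighbors (boundary included). The returned matrix is
#' restricted to transient rows and columns, so its rows sum to at most
#' `damping` (strictly less where mass flows to boundary nodes or zero
#' where a transient node is isolated).
#'
#' @param graph a [WTGGN-class] or a square non-negative weight matrix with
#'   matching dimnames (undirected graphs as symmetric matrices).
#' @param boundary character vector of boundary node ids (may be empty).
#' @param config a [WalkConfig-class].
#' @return sparse row-substochastic matrix over transient nodes.
#' @export
transitionMatrix <- function(graph, boundary = character(),
                             config = walkConfig()) {
  W <- .walkMatrix(graph)
  sys <- .walkSystem(W, boundary, config@damping)
  sys$M
}

#' Expected visits of the emitting model
#'
#' A damped walker is injected at `source` and wanders until it dissipates
#' or reaches a sink. The expected number of visits v(u) to every transient
#' node (the source is transient and counts its initial visit) solves the
#' linear system `v = e_source + M' v`, where M is the damped transient
#' transition matrix. The solution is certified by a relative residual
#' bound.
#'
#' @inheritParams transitionMatrix
#' @param source the emitting node (transient; must not be a sink).
#' @param sinks character vector of absorbing nodes (may be empty).
#' @return named numeric vector of expected visits over transient nodes.
#' @export
emittingVisits <- function(graph, source, sinks = character(),
                           config = walkConfig()) {
  W <- .walkMatrix(graph)
  sys <- .walkSystem(W, sinks, config@damping)
  if (!source %in% sys$transient)
    .stopf("source '%s' must be a transient (non-sink) node", source)
  n <- length(sys$transient)
  e <- as.numeric(sys$transient == source)
  A <- Matrix::Diagonal(n) - Matrix::t(sys$M)
  v <- .solveCertified(A, e, config@tolerance, "emitting")
  setNames(v, sys$transient)
}

#' Absorption probabilities of the absorbing model
#'
#' a(u) is the probability that a damped walker starting at transient node
#' u ever reaches one of the sinks before dissipating; it solves
#' `a = M a + r` with r(u) the damped one-step probability of entering a
#' sink from u. All values lie in [0, 1].
#'
#' @inheritParams transitionMatrix
#' @param sinks nonempty character vector of absorbing nodes.
#' @return named numeric vector of probabilities over transient nodes.
#' @export
absorbingProbability <- function(graph, sinks, config = walkConfig()) {
  if (!length(sinks)) .stopf("absorbing model requires at least one sink")
  W <- .walkMatrix(graph)
  sys <- .walkSystem(W, sinks, config@damping)
  r <- Matrix::rowSums(sys$R)
  A <- Matrix::Diagonal(length(sys$transient)) - sys$M
  a <- .solveCertified(A, r, config@tolerance, "absorbing")
  a <- pmin(pmax(a, 0), 1)
  setNames(a, sys$transient)
}

#' Conditioned expected visits of the channel model
#'
#' Expected visits by a walker injected at `source` and conditioned on
#' eventual absorption at the sink(s): `h(u) = v(u) a(u) / a(source)`,
#' where v are the emitting visits with the sinks absorbing and a the
#' absorption probabilities. When source equals a sink the node is split
#' into an emit-only source copy and an absorb-only sink copy carrying the
#' same edges (the walker leaves the node, wanders, and is counted only if
#' it returns).
#'
#' @inheritParams transitionMatrix
#' @param source the emitting node.
#' @param sink character vector of absorbing node(s).
#' @return named numeric vector of conditioned expected visits over
#'   transient nodes; an empty vector (with a warning) when the sinks are
#'   unreachable from the source.
#' @export
channelVisits <- function(graph, source, sink, config = walkConfig()) {
  W <- .walkMatrix(graph)
  if (source %in% sink) {
    if (length(sink) != 1L)
      .stopf("source = sink channel requires a single sink")
    W <- .splitSource(W, source)
    h <- .channelCore(W, ".__source__.", sink, config)
    return(h[setdiff(names(h), ".__source__.")])
  }
  .channelCore(W, source, sink, config)
}

# Split node s into an emit-only copy ".__source__." (keeps s's outgoing
# edges) while s itself keeps only incoming edges and acts as the sink.
.splitSource <- function(W, s) {
  nodes <- rownames(W)
  if (!s %in% nodes) .stopf("unknown node: %s", s)
  srcName <- ".__source__."
  if (srcName %in% nodes) .stopf("reserved node name in graph: %s", srcName)
  W2 <- rbind(W, W[s, , drop = FALSE])
  W2 <- cbind(W2, 0)
  rownames(W2) <- c(nodes, srcName)
  colnames(W2) <- c(nodes, srcName)
  W2[s, ] <- 0
  W2
}

.channelCore <- function(W, source, sinks, config) {
  sys <- .walkSystem(W, sinks, config@damping)
  if (!source %in% sys$transient)
    .stopf("source '%s' must be a transient (non-sink) node", source)
  n <- length(sys$transient)
  e <- as.numeric(sys$transient == source)
  v <- .solveCertified(Matrix::Diagonal(n) - Matrix::t(sys$M), e,
                       config@tolerance, "channel emitting")
  r <- Matrix::rowSums(sys$R)
  a <- .solveCertified(Matrix::Diagonal(n) - sys$M, r,
                       config@tolerance, "channel absorbing")
  a <- pmin(pmax(a, 0), 1)
  names(v) <- names(a) <- sys$transient
  if (a[[source]] <= 0) {
    .warnf("sink unreachable from source '%s'; empty channel vector", source)
    return(setNames(numeric(0), character(0)))
  }
  h <- v * a / a[[source]]
  h[v == 0 | a == 0] <- 0
  h
}

#' Probability bookkeeping of the emitting model
#'
#' Recovers, from the solved emitting system, the total probability mass
#' absorbed at the sinks and the mass lost to dissipation. For a damped
#' walk these sum to 1 (up to solver tolerance).
#'
#' @inheritParams emittingVisits
#' @return list with elements `absorbed` and `dissipated`.
#' @export
flowConservation <- function(graph, source, sinks = character(),
                             config = walkConfig()) {
  W <- .walkMatrix(graph)
  sys <- .walkSystem(W, sinks, config@damping)
  if (!source %in% sys$transient)
    .stopf("source '%s' must be a transient (non-sink) node", source)
  n <- length(sys$transient)
  e <- as.numeric(sys$transient == source)
  v <- .solveCertified(Matrix::Diagonal(n) - Matrix::t(sys$M), e,
                       config@tolerance, "emitting")
  rt <- sys$rowTot[sys$transient]
  absorbed <- sum(v * Matrix::rowSums(sys$R))
  # each visit dissipates with probability 1 - damping, or with certainty
  # when the node has no outgoing weight at all
  dissipated <- sum(v * ifelse(rt > 0, 1 - config@damping, 1))
  list(absorbed = absorbed, dissipated = dissipated)
}

#' Represent a term as a gene visit-weight vector
#'
#' Runs the channel model with the term as both source and sink by node
#' splitting: the walker leaves a source copy of the term through its
#' annotation edges, wanders the gene-gene network, and is absorbed on
#' returning to the sink copy (or dissipates). All other term nodes are
#' removed from the walk graph, so flow travels only through gene-gene
#' connectivity plus the focal term's own annotation edges; pass
#' `termsTransient = TRUE` to keep them as transient nodes instead. The
#' result is the N-dimensional vector of conditioned expected visits over
#' all gene nodes of the network (zero for genes never visited).
#'
#' @param graph a [WTGGN-class].
#' @param term a term node of the network.
#' @param config a [WalkConfig-class].
#' @param termsTransient keep non-focal term nodes in the walk graph.
#' @return a [TermVector-class] over all gene nodes of `graph`.
#' @export
termVector <- function(graph, term, config = walkConfig(),
                       termsTransient = FALSE) {
  stopifnot(is(graph, "WTGGN"))
  if (!term %in% graph@termNodes)
    .stopf("'%s' is not a term node of the network", term)
  tg <- graph@tgEdges
  own <- tg[tg$term == term, , drop = FALSE]
  if (nrow(own) == 0L || all(own$weight == 0)) {
    if (nrow(own) == 0L)
      .stopf("term '%s' has no surviving annotation edges", term)
  }
  gg <- graph@ggEdges
  geneNodes <- graph@geneNodes
  srcName <- ".__source__."
  nodes <- c(geneNodes, term, srcName)
  if (termsTransient) {
    others <- setdiff(graph@termNodes, term)
    nodes <- c(geneNodes, others, term, srcName)
  }
  idx <- setNames(seq_along(nodes), nodes)

  i <- c(idx[gg$gene1], idx[gg$gene2])
  j <- c(idx[gg$gene2], idx[gg$gene1])
  w <- c(gg$weight, gg$weight)
  # focal term: source copy emits, original node absorbs returning walkers
  i <- c(i, idx[rep(srcName, nrow(own))], idx[own$gene])
  j <- c(j, idx[own$gene], idx[rep(term, nrow(own))])
  w <- c(w, own$weight, own$weight)
  if (termsTransient) {
    oth <- tg[tg$term != term, , drop = FALSE]
    i <- c(i, idx[oth$term], idx[oth$gene])
    j <- c(j, idx[oth$gene], idx[oth$term])
    w <- c(w, oth$weight, oth$weight)
  }
  W <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  h <- .channelCore(W, srcName, term, config)
  out <- setNames(numeric(length(geneNodes)), geneNodes)
  hit <- intersect(names(h), geneNodes)
  out[hit] <- h[hit]
  new("TermVector", term = term, weights = out)
}

#' @rdname visitWeights
#' @export
setMethod("visitWeights", "TermVector", function(x) x@weights)

#' @export
setMethod("show", "TermVector", function(object) {
  w <- object@weights
  cat(sprintf("TermVector for %s: %d genes, %d visited (max weight %.4g)\n",
              object@term, length(w), sum(w > 0),
              if (length(w)) max(w) else 0))
})

#' Dump per-term vectors to TSV
#'
#' @param vectors list of [TermVector-class] objects.
#' @param path output path; columns term, gene, weight.
#' @return `path`, invisibly.
#' @export
writeTermVectors <- function(vectors, path) {
  rows <- lapply(vectors, function(v)
    .df(term = v@term, gene = names(v@weights),
        weight = sprintf("%.17g", v@weights)))
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
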