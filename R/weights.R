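#' Information weight of a term-gene pair (bits)
#'
#' `-log2(n_j / N_T)`: a gene annotated by few of the N_T annotation terms
#' carries more information about each of them, so its term-gene pairs
#' weigh more.
#'
#' @param nj number of terms associated with the gene (1 <= nj <= NT).
#' @param NT total number of annotation terms.
#' @return non-negative weight in bits (vectorized over `nj`).
#' @examples
#' termGeneWeight(2, 8)  # 2 bits
#' @export
termGeneWeight <- function(nj, NT) {
  if (any(nj < 1) || any(nj > NT)) .stopf("require 1 <= nj <= NT")
  -log2(nj / NT)
}

#' Information weight of a term (bits)
#'
#' `-log2(n_g / N_G)`: terms annotating fewer of the N_G annotated genes get
#' higher weight, counteracting shallow annotation (high-level DAG terms
#' annotate many genes once annotations are propagated).
#'
#' @param ng number of genes annotated by the term (1 <= ng <= NG).
#' @param NG total number of annotated genes.
#' @return non-negative weight in bits (vectorized over `ng`); strictly
#'   decreasing in `ng`.
#' @export
termWeight <- function(ng, NG) {
  if (any(ng < 1) || any(ng > NG)) .stopf("require 1 <= ng <= NG")
  -log2(ng / NG)
}

#' Min-max normalization to the unit interval
#'
#' Maps each value v to (v - min) / (max - min). When all values are equal
#' the output is defined as 1 for every element, so a uniformly weighted
#' network keeps its connectivity instead of vanishing.
#'
#' @param values numeric vector (names preserved); must be non-empty and
#'   finite.
#' @return numeric vector in [0, 1].
#' @export
minmaxNormalize <- function(values) {
  if (length(values) == 0L) .stopf("minmaxNormalize: empty input")
  if (any(!is.finite(values))) .stopf("minmaxNormalize: non-finite values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(setNames(rep(1, length(values)), names(values)))
  (values - lo) / (hi - lo)
}

#' Compute term-gene and term weight tables
#'
#' Computes raw information weights for every unique (term, gene) pair and
#' every term of an annotation set, then min-max normalizes each. By
#' default the normalization pools all terms (both ontologies together,
#' since the downstream network is a single graph); pass `termGroups` to
#' min-max within groups instead. `termWeightFloor` optionally clamps
#' normalized term weights from below (the most-annotated term otherwise
#' gets weight exactly 0, which annihilates all its similarities).
#'
#' @param annotations an [AnnotationSet-class] (typically after
#'   [propagateAnnotations()]).
#' @param termGroups optional named character vector mapping term id to a
#'   group label; normalization is then done within each group.
#' @param termWeightFloor lower clamp for normalized term weights
#'   (default 0, the faithful formula).
#' @return a [WeightTable-class].
#' @export
computeWeights <- function(annotations, termGroups = NULL,
                           termWeightFloor = 0) {
  stopifnot(is(annotations, "AnnotationSet"))
  pairs <- annotationPairs(annotations)
  if (nrow(pairs) == 0L) .stopf("no annotations to weight")
  nj <- nTermsPerGene(annotations)
  ng <- nGenesPerTerm(annotations)
  NT <- length(ng)
  NG <- length(nj)

  tgRaw <- termGeneWeight(unname(nj[pairs$gene]), NT)
  tRaw <- termWeight(unname(ng), NG)

  normWithin <- function(raw, keys) {
    if (is.null(termGroups)) return(minmaxNormalize(raw))
    grp <- termGroups[keys]
    if (any(is.na(grp)))
      .stopf("termGroups is missing %d term(s)", sum(is.na(grp)))
    out <- numeric(length(raw))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      out[idx] <- minmaxNormalize(raw[idx])
    }
    out
  }

  tg <- .df(term = pairs$term, gene = pairs$gene, raw = tgRaw,
            norm = normWithin(tgRaw, pairs$term))
  tw <- .df(term = names(ng), raw = tRaw,
            norm = pmax(normWithin(tRaw, names(ng)), termWeightFloor))
  tg <- tg[.orderC(tg$term, tg$gene), , drop = FALSE]
  tw <- tw[.orderC(tw$term), , drop = FALSE]
  rownames(tg) <- rownames(tw) <- NULL
  new("WeightTable", termGene = tg, term = tw)
}

#' Read a gene functional-interaction network edge list
#'
#' Three-column whitespace/tab separated file: gene, gene, functional
#' interaction score (HumanNet/YeastNet style). Lines starting with `#`
#' are skipped; a non-numeric first row is treated as a header.
#'
#' @param path path to the edge-list file.
#' @return data.frame with columns `gene1`, `gene2`, `score`.
#' @export
readGFIN <- function(path) {
  if (!file.exists(path)) .stopf("GFIN file not found: %s", path)
  df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                   colClasses = c("character", "character", "character"),
                   col.names = c("gene1", "gene2", "score"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$score[[1L]]))))
    df <- df[-1L, , drop = FALSE]
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score))) .stopf("non-numeric GFIN scores in %s", path)
  rownames(df) <- NULL
  df
}

#' Min-max normalize functional-interaction scores
#'
#' Cleans an undirected edge list (removes self loops; collapses duplicate
#' undirected edges keeping the maximum score) and min-max normalizes the
#' retained scores to [0, 1]. The edge attaining the minimum score gets
#' weight 0; it stays in the edge list but contributes no transition
#' probability to the random walk.
#'
#' @param edges data.frame with columns `gene1`, `gene2`, `score` (as from
#'   [readGFIN()]).
#' @return data.frame with columns `gene1`, `gene2`, `weight`; one row per
#'   undirected edge with `gene1 < gene2`.
#' @export
normalizeGFIN <- function(edges) {
  stopifnot(all(c("gene1", "gene2", "score") %in% colnames(edges)))
  if (any(!is.finite(edges$score))) .stopf("non-finite FIS scores")
  keep <- edges$gene1 != edges$gene2
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) == 0L) .stopf("no gene-gene edges after removing self loops")
  a <- pmin(e$gene1, e$gene2)
  b <- pmax(e$gene1, e$gene2)
  key <- paste(a, b, sep = "\r")
  score <- vapply(split(e$score, key), max, 0)
  keys <- strsplit(names(score), "\r", fixed = TRUE)
  out <- .df(gene1 = vapply(keys, `[[`, "", 1L),
             gene2 = vapply(keys, `[[`, "", 2L),
             weight = unname(minmaxNormalize(unname(score))))
  out <- out[.orderC(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a weight table to TSV for inspection
#'
#' @param weights a [WeightTable-class].
#' @param termGenePath,termPath output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
writeWeightTable <- function(weights, termGenePath = NULL, termPath = NULL) {
  stopifnot(is(weights, "WeightTable"))
  if (!is.null(termGenePath))
    write.table(weights@termGene, termGenePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(termPath))
    write.table(weights@term, termPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(termGene = termGenePath, term = termPath))
}

#' @export
setMethod("show", "WeightTable", function(object) {
  cat(sprintf("WeightTable: %d term-gene pairs, %d terms\n",
              nrow(object@termGene), nrow(object@term)))
})
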