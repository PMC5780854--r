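#' Sample a negative group of cross-ontology term pairs
#'
#' Uniform sampling without replacement over the cross product of the two
#' annotated-term universes, excluding the positive pairs. Terms may recur
#' across sampled pairs; only the pairs themselves are unique. Reproducible
#' under `seed`.
#'
#' @param positives data.frame with columns `term_a`, `term_b` (the
#'   positive group).
#' @param termsA,termsB character vectors: the annotated-term universes of
#'   the two ontologies.
#' @param ratio how many negatives per positive (default 10).
#' @param seed RNG seed.
#' @return data.frame with columns `term_a`, `term_b` and
#'   `ratio * nrow(positives)` rows.
#' @export
sampleNegatives <- function(positives, termsA, termsB, ratio = 10L, seed) {
  stopifnot(all(c("term_a", "term_b") %in% colnames(positives)))
  nNeg <- as.integer(ratio) * nrow(positives)
  if (nNeg == 0L) return(.df(term_a = character(), term_b = character()))
  nA <- length(termsA); nB <- length(termsB)
  posKey <- paste(positives$term_a, positives$term_b, sep = "\r")
  universe <- as.numeric(nA) * nB - length(unique(posKey))
  if (universe < nNeg)
    .stopf(paste0("pair universe too small: %d x %d terms minus %d ",
                  "positives < %d requested negatives"),
           nA, nB, length(unique(posKey)), nNeg)
  set.seed(seed)
  chosen <- character(0)
  while (length(chosen) < nNeg) {
    need <- nNeg - length(chosen)
    ia <- sample.int(nA, 2L * need + 10L, replace = TRUE)
    ib <- sample.int(nB, 2L * need + 10L, replace = TRUE)
    key <- paste(termsA[ia], termsB[ib], sep = "\r")
    key <- key[!(key %in% posKey) & !(key %in% chosen)]
    chosen <- c(chosen, unique(key))
  }
  chosen <- chosen[seq_len(nNeg)]
  parts <- strsplit(chosen, "\r", fixed = TRUE)
  .df(term_a = vapply(parts, `[[`, "", 1L),
      term_b = vapply(parts, `[[`, "", 2L))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, ties credited 1/2. This is the
#' limit of trapezoidal integration of the threshold-swept ROC curve.
#'
#' @param posScores,negScores numeric score vectors (both nonempty).
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(2, 3), c(1, 3))  # 0.625
#' @export
rocAUC <- function(posScores, negScores) {
  if (!length(posScores) || !length(negScores))
    .stopf("both score lists must be nonempty")
  r <- rank(c(posScores, negScores))
  np <- length(posScores); nn <- length(negScores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Repeated-negative-sampling AUC
#'
#' Draws a fresh negative group per iteration (seed = `baseSeed + i`),
#' scores it with `scorer`, and reports the mean, population standard
#' deviation and full list of per-iteration AUCs against the (once-scored)
#' positive group.
#'
#' @param scorer function taking a data.frame with columns `term_a`,
#'   `term_b` and returning numeric scores (see [infacrontScorer()],
#'   [vsmScorer()]).
#' @param positives data.frame of positive pairs (`term_a`, `term_b`).
#' @param termsA,termsB annotated-term universes for negative sampling.
#' @param iterations number of negative groups (>= 1).
#' @param ratio negatives per positive.
#' @param baseSeed base RNG seed; iteration i uses `baseSeed + i`.
#' @return list with `mean`, `sd` (population SD), `aucs`.
#' @export
iterateAUC <- function(scorer, positives, termsA, termsB, iterations = 100L,
                       ratio = 10L, baseSeed = 1L) {
  stopifnot(iterations >= 1L)
  posScores <- scorer(positives)
  aucs <- vapply(seq_len(iterations), function(i) {
    neg <- sampleNegatives(positives, termsA, termsB, ratio = ratio,
                           seed = baseSeed + i)
    rocAUC(posScores, scorer(neg))
  }, 0)
  n <- length(aucs)
  list(mean = mean(aucs),
       sd = sqrt(sum((aucs - mean(aucs))^2) / n),
       aucs = aucs)
}

#' TF-IDF scores of a co-occurrence count matrix
#'
#' For a disease-by-phenotype occurrence-count matrix, score(i, j) =
#' tf(i, j) * idf(j) with tf the raw count and
#' `idf(j) = log2(N_rows / df(j))`, df(j) being the number of rows in
#' which column j has a positive count. Columns occurring in every row get
#' idf 0; all-zero columns score 0 throughout.
#'
#' @param counts non-negative numeric matrix (rows: diseases, columns:
#'   phenotypes).
#' @return matrix of the same shape with TF-IDF scores.
#' @export
tfidfSimilarity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  df <- colSums(counts > 0)
  idf <- ifelse(df > 0, log2(nrow(counts) / df), 0)
  sweep(counts, 2L, idf, `*`)
}

#' Pearson correlation between two score vectors
#'
#' Thin wrapper around [stats::cor()] / [stats::cor.test()] returning the
#' correlation coefficient, its square and the test p-value.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `r2`, `p.value`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .stopf("need equal-length vectors with at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("Pearson correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p.value = ct$p.value)
}

#' Benchmark a scorer set on a synthetic fixture
#'
#' Convenience driver used by the worked examples: builds the
#' term-gene-gene network from a generated fixture (propagated
#' annotations, pooled weights, normalized interaction scores), then runs
#' [iterateAUC()] for the requested methods against the fixture's planted
#' positive pairs.
#'
#' @param fixture result of [generateSynthetic()].
#' @param methods subset of `c("infacront", "vsm")`.
#' @param iterations,ratio,baseSeed passed to [iterateAUC()].
#' @param config a [WalkConfig-class] for the channel walk.
#' @return list with one entry per method (each a [iterateAUC()] result)
#'   plus `graph`, the assembled [WTGGN-class].
#' @export
benchmarkAUC <- function(fixture, methods = c("infacront", "vsm"),
                         iterations = 20L, ratio = 10L, baseSeed = 1L,
                         config = walkConfig()) {
  methods <- match.arg(methods, several.ok = TRUE)
  onts <- list(fixture$ontologyA, fixture$ontologyB)
  ann <- propagateAnnotations(fixture$annotations, onts)
  wt <- computeWeights(ann)
  gfin <- normalizeGFIN(fixture$gfin)
  graph <- buildWTGGN(ann, wt, gfin)

  annotated <- terms(ann)
  termsA <- intersect(annotated, terms(fixture$ontologyA))
  termsB <- intersect(annotated, terms(fixture$ontologyB))

  out <- list(graph = graph)
  for (m in methods) {
    scorer <- switch(m,
      infacront = infacrontScorer(graph, config),
      vsm = vsmScorer(ann))
    out[[m]] <- iterateAUC(scorer, fixture$positives, termsA, termsB,
                           iterations = iterations, ratio = ratio,
                           baseSeed = baseSeed)
  }
  out
}
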