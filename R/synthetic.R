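#' Specification for a synthetic cross-ontology benchmark
#'
#' Defines the study conditions emulated by [generateSynthetic()]: two
#' random rooted IS_A DAGs, leaf-biased annotations over a shared gene
#' pool, a weighted gene functional-interaction network, and planted
#' positive term pairs. Generation is a pure function of the spec: the
#' same spec yields byte-identical files.
#'
#' Planted signal comes in two flavors. `plantedMode = "shared"` gives the
#' two terms of a pair overlapping annotated gene sets
#' (`plantedOverlap` fraction shared); `plantedMode = "adjacent"` gives
#' them disjoint gene sets but connects the two sets completely in the
#' interaction network, a signal only methods exploiting network
#' connectivity can see (the annotation-overlap baseline scores such pairs
#' exactly 0).
#'
#' @param nTermsA,nTermsB number of terms per ontology.
#' @param dagBranching mean number of IS_A parents per non-root term.
#' @param nGenes size of the gene pool.
#' @param annotationRate mean number of genes annotated per leaf term.
#' @param gfinModel `"scale-free"` (preferential attachment) or
#'   `"erdos-renyi"`.
#' @param gfinMeanDegree mean gene degree of the interaction network.
#' @param fisMeanlog,fisSdlog log-normal parameters of the raw functional
#'   interaction scores.
#' @param nPlantedPairs number of planted positive cross-ontology pairs.
#' @param plantedOverlap fraction of each planted pair's annotated genes
#'   that are shared, in [0, 1] (0 is the null configuration: planted
#'   pairs carry no signal).
#' @param plantedMode `"shared"` or `"adjacent"` (see Details).
#' @param seed RNG seed; all randomness derives from it.
#' @return an object of class `SyntheticSpec` (a validated list).
#' @export
syntheticSpec <- function(nTermsA = 30L, nTermsB = 30L, dagBranching = 1.3,
                          nGenes = 150L, annotationRate = 6,
                          gfinModel = c("scale-free", "erdos-renyi"),
                          gfinMeanDegree = 4, fisMeanlog = 0, fisSdlog = 1,
                          nPlantedPairs = 8L, plantedOverlap = 0.8,
                          plantedMode = c("shared", "adjacent"), seed = 1L) {
  spec <- list(
    nTermsA = as.integer(nTermsA), nTermsB = as.integer(nTermsB),
    dagBranching = dagBranching, nGenes = as.integer(nGenes),
    annotationRate = annotationRate, gfinModel = match.arg(gfinModel),
    gfinMeanDegree = gfinMeanDegree, fisMeanlog = fisMeanlog,
    fisSdlog = fisSdlog, nPlantedPairs = as.integer(nPlantedPairs),
    plantedOverlap = plantedOverlap, plantedMode = match.arg(plantedMode),
    seed = as.integer(seed))
  with(spec, {
    if (nTermsA < 2L || nTermsB < 2L || nGenes < 2L || nPlantedPairs < 0L)
      .stopf("counts must be positive (>= 2 terms and genes)")
    if (dagBranching < 1 || annotationRate <= 0 || gfinMeanDegree <= 0)
      .stopf("rates must be positive (dagBranching >= 1)")
    if (plantedOverlap < 0 || plantedOverlap > 1)
      .stopf("plantedOverlap must lie in [0, 1]")
  })
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic cross-ontology benchmark
#'
#' Writes a complete synthetic input set in the standard formats — two OBO
#' ontologies, one GAF annotation file, a 3-column interaction edge list
#' and the planted positive pairs as TSV — and returns both the file paths
#' and the objects produced by re-reading the files through the package's
#' own parsers (so every generated artifact round-trips through the real
#' readers).
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return list with elements `ontologyA`, `ontologyB` ([Ontology-class]),
#'   `annotations` ([AnnotationSet-class]), `gfin` (data.frame),
#'   `positives` (data.frame `term_a`, `term_b`), `files` (named paths)
#'   and `spec`.
#' @export
generateSynthetic <- function(spec, dir = tempfile("synthetic")) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  genePool <- sprintf("G%04d", seq_len(spec$nGenes))
  ontA <- .randomDAG("SYNA", spec$nTermsA, spec$dagBranching)
  ontB <- .randomDAG("SYNB", spec$nTermsB, spec$dagBranching)
  leavesA <- setdiff(ontA$terms, unique(ontA$edges$parent))
  leavesB <- setdiff(ontB$terms, unique(ontB$edges$parent))

  if (length(leavesA) < spec$nPlantedPairs ||
      length(leavesB) < spec$nPlantedPairs)
    .stopf("infeasible spec: %d planted pairs but only %d / %d leaf terms",
           spec$nPlantedPairs, length(leavesA), length(leavesB))

  plantedA <- sample(leavesA, spec$nPlantedPairs)
  plantedB <- sample(leavesB, spec$nPlantedPairs)

  ann <- list()
  plantedGenes <- list()
  for (k in seq_len(spec$nPlantedPairs)) {
    # both terms of a planted pair annotate the same number of genes, so
    # plantedOverlap = 1 means identical gene sets
    nG <- max(2L, rpois(1L, spec$annotationRate))
    if (spec$plantedMode == "shared" && spec$plantedOverlap > 0) {
      nShared <- max(1L, round(spec$plantedOverlap * nG))
      if (2L * nG - nShared > spec$nGenes)
        .stopf("infeasible spec: planted gene sets exceed the gene pool")
      shared <- sample(genePool, nShared)
      extraA <- sample(setdiff(genePool, shared), nG - nShared)
      extraB <- sample(setdiff(genePool, c(shared, extraA)), nG - nShared)
      ga <- c(shared, extraA); gb <- c(shared, extraB)
    } else {
      ga <- sample(genePool, nG)
      gb <- sample(setdiff(genePool, ga), nG)
    }
    ann[[length(ann) + 1L]] <- .df(term = plantedA[[k]], gene = ga)
    ann[[length(ann) + 1L]] <- .df(term = plantedB[[k]], gene = gb)
    plantedGenes[[k]] <- list(a = ga, b = gb)
  }
  for (t in setdiff(c(leavesA, leavesB), c(plantedA, plantedB))) {
    k <- max(1L, rpois(1L, spec$annotationRate))
    ann[[length(ann) + 1L]] <- .df(term = t, gene = sample(genePool, k))
  }
  annDf <- unique(do.call(rbind, ann))
  annDf$evidence <- sample(c("EXP", "IDA", "IMP"), nrow(annDf),
                           replace = TRUE)
  # sprinkle a few electronic annotations the default pipeline filters out
  nIEA <- max(1L, round(0.05 * nrow(annDf)))
  iea <- .df(term = sample(c(leavesA, leavesB), nIEA, replace = TRUE),
             gene = sample(genePool, nIEA, replace = TRUE),
             evidence = "IEA")
  annDf <- unique(rbind(annDf, iea))

  gfin <- .randomGFIN(genePool, spec)
  if (spec$plantedMode == "adjacent" && spec$nPlantedPairs > 0L) {
    extra <- do.call(rbind, lapply(plantedGenes, function(pg) {
      grid <- expand.grid(gene1 = pg$a, gene2 = pg$b,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$score <- rlnorm(nrow(grid), spec$fisMeanlog, spec$fisSdlog)
      grid
    }))
    gfin <- rbind(gfin, extra)
  }

  positives <- .df(term_a = plantedA, term_b = plantedB)
  positives <- positives[.orderC(positives$term_a), , drop = FALSE]
  rownames(positives) <- NULL

  files <- c(oboA = file.path(dir, "ontology_a.obo"),
             oboB = file.path(dir, "ontology_b.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             gfin = file.path(dir, "gfin.tsv"),
             positives = file.path(dir, "positives.tsv"))
  .writeSyntheticOBO(ontA, files[["oboA"]])
  .writeSyntheticOBO(ontB, files[["oboB"]])
  .writeGAF(annDf, files[["gaf"]])
  .writeGFIN(gfin, files[["gfin"]])
  write.table(positives, files[["positives"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(ontologyA = parseOBO(files[["oboA"]]),
       ontologyB = parseOBO(files[["oboB"]]),
       annotations = parseGAF(files[["gaf"]]),
       gfin = readGFIN(files[["gfin"]]),
       positives = positives,
       files = files, spec = spec)
}

# Rooted random DAG: term i >= 2 draws 1 + Pois(branching - 1) parents
# among terms 1..i-1 (term 1 is the root).
.randomDAG <- function(prefix, nTerms, branching) {
  ids <- sprintf("%s:%07d", prefix, seq_len(nTerms))
  child <- character(); parent <- character()
  for (i in seq(2L, nTerms)) {
    k <- min(i - 1L, 1L + rpois(1L, branching - 1))
    ps <- if (i == 2L) 1L else sample.int(i - 1L, k)
    child <- c(child, rep(ids[[i]], length(ps)))
    parent <- c(parent, ids[ps])
  }
  list(terms = ids, edges = .df(child = child, parent = parent),
       names = setNames(sprintf("synthetic term %d", seq_len(nTerms)), ids))
}

.randomGFIN <- function(genePool, spec) {
  n <- length(genePool)
  g <- if (spec$gfinModel == "scale-free") {
    igraph::sample_pa(n, m = max(1L, round(spec$gfinMeanDegree / 2)),
                      directed = FALSE)
  } else {
    igraph::sample_gnp(n, p = min(1, spec$gfinMeanDegree / (n - 1)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  .df(gene1 = genePool[el[, 1L]], gene2 = genePool[el[, 2L]],
      score = rlnorm(nrow(el), spec$fisMeanlog, spec$fisSdlog))
}

.writeSyntheticOBO <- function(ont, path) {
  parentsOf <- split(ont$edges$parent, ont$edges$child)
  out <- c("format-version: 1.2", "")
  for (t in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", ont$names[[t]]))
    for (p in .sortC(parentsOf[[t]])) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path)
}

.writeGAF <- function(annDf, path) {
  annDf <- annDf[.orderC(annDf$term, annDf$gene, annDf$evidence), ,
                 drop = FALSE]
  lines <- sprintf(
    "SYN\t%s\t%s\t\t%s\tSYN_REF:0000001\t%s\t\tP\t%s\t\tgene\ttaxon:0\t20260101\tSYN\t\t",
    annDf$gene, annDf$gene, annDf$term, annDf$evidence, annDf$gene)
  writeLines(c("!gaf-version: 2.1", lines), path)
}

.writeGFIN <- function(gfin, path) {
  # duplicate planted edges may coexist with sampled ones; the normalizer
  # collapses them, but keep the file clean and deterministic
  a <- pmin(gfin$gene1, gfin$gene2); b <- pmax(gfin$gene1, gfin$gene2)
  df <- .df(gene1 = a, gene2 = b, score = gfin$score)
  df <- df[.orderC(df$gene1, df$gene2, sprintf("%.17g", df$score)), ,
           drop = FALSE]
  writeLines(sprintf("%s\t%s\t%.10g", df$gene1, df$gene2, df$score), path)
}
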