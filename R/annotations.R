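#' Parse a GAF annotation file
#'
#' Reads a tab-separated GAF 2.x gene association file. Comment lines
#' starting with `!` are skipped. Columns used: 2 (gene/object id),
#' 4 (qualifier), 5 (term id), 7 (evidence code). Records whose evidence
#' code is in `excludeEvidence` (by default `"IEA"`, the non-curated
#' electronic annotations) are dropped, as are NOT-qualified records.
#' Duplicate records are collapsed. If an `ontology` (or list of
#' ontologies) is supplied, alternative term ids are mapped to their
#' primary id.
#'
#' @param path path to a GAF file.
#' @param excludeEvidence character vector of evidence codes to drop.
#' @param ontology optional [Ontology-class] or list of them, used only to
#'   resolve alt_id term identifiers.
#' @return an [AnnotationSet-class].
#' @export
parseGAF <- function(path, excludeEvidence = "IEA", ontology = NULL) {
  if (!file.exists(path)) .stopf("GAF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\r$", "", lines)
  dataIdx <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))
  fields <- strsplit(lines[dataIdx], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  bad <- which(nf < 15L)
  if (length(bad))
    .stopf("GAF line %d has %d columns (expected >= 15)",
           dataIdx[[bad[[1L]]]], nf[[bad[[1L]]]])
  if (!length(fields)) {
    .warnf("no annotation records in %s", path)
    return(new("AnnotationSet"))
  }
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)

  keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier) &
    !(evidence %in% excludeEvidence)
  rec <- unique(.df(term = term[keep], gene = gene[keep],
                    evidence = evidence[keep]))
  if (!is.null(ontology)) rec <- .mapAltIds(rec, ontology)
  if (nrow(rec) == 0L)
    .warnf("all annotation records filtered out of %s", path)
  rec <- rec[.orderC(rec$term, rec$gene, rec$evidence), , drop = FALSE]
  rownames(rec) <- NULL
  new("AnnotationSet", records = rec)
}

.mapAltIds <- function(rec, ontology) {
  onts <- if (is(ontology, "Ontology")) list(ontology) else ontology
  for (ont in onts) {
    alt <- ont@altIds
    hit <- rec$term %in% names(alt)
    if (any(hit)) rec$term[hit] <- unname(alt[rec$term[hit]])
  }
  unique(rec)
}

#' Propagate annotations to ancestor terms
#'
#' If a gene is annotated by a term it is also annotated by every ancestor
#' of that term along IS_A edges (the set-inclusion reading of IS_A).
#' Propagated records inherit the evidence code of the record they derive
#' from. Terms absent from the supplied ontologies are reported and
#' dropped. Propagation is idempotent.
#'
#' @param annotations an [AnnotationSet-class].
#' @param ontology an [Ontology-class] or a list of them (annotation terms
#'   are looked up in their union; alt_ids are resolved first).
#' @return an [AnnotationSet-class] with counts recomputed.
#' @export
propagateAnnotations <- function(annotations, ontology) {
  stopifnot(is(annotations, "AnnotationSet"))
  onts <- if (is(ontology, "Ontology")) list(ontology) else ontology
  rec <- .mapAltIds(annotations@records, onts)

  allTerms <- unlist(lapply(onts, function(o) o@terms), use.names = FALSE)
  unknown <- setdiff(unique(rec$term), allTerms)
  if (length(unknown)) {
    message(sprintf("dropping %d annotation term(s) not in the ontologies: %s",
                    length(unknown),
                    paste(head(.sortC(unknown), 5L), collapse = ", ")))
    rec <- rec[!(rec$term %in% unknown), , drop = FALSE]
  }

  anc <- do.call(c, lapply(onts, .ancestorClosure))
  nAnc <- vapply(anc[rec$term], length, 1L)
  extra <- .df(
    term = unlist(anc[rec$term], use.names = FALSE),
    gene = rep(rec$gene, nAnc),
    evidence = rep(rec$evidence, nAnc)
  )
  out <- unique(rbind(rec, extra))
  out <- out[.orderC(out$term, out$gene, out$evidence), , drop = FALSE]
  rownames(out) <- NULL
  new("AnnotationSet", records = out)
}

#' Keep only annotations with allowed evidence codes
#'
#' @param annotations an [AnnotationSet-class].
#' @param excludeEvidence evidence codes to drop.
#' @return an [AnnotationSet-class].
#' @export
filterEvidence <- function(annotations, excludeEvidence = "IEA") {
  rec <- annotations@records
  rec <- rec[!(rec$evidence %in% excludeEvidence), , drop = FALSE]
  rownames(rec) <- NULL
  new("AnnotationSet", records = rec)
}

#' @rdname annotationPairs
#' @export
setMethod("annotationPairs", "AnnotationSet", function(x) {
  p <- unique(x@records[, c("term", "gene")])
  rownames(p) <- NULL
  p
})

#' @describeIn parseGAF distinct annotation terms (N_T is their count).
#' @param x an [AnnotationSet-class].
#' @param ... ignored.
#' @export
setMethod("terms", "AnnotationSet", function(x, ...) {
  .sortC(unique(x@records$term))
})

#' @rdname genes
#' @export
setMethod("genes", "AnnotationSet", function(x) {
  .sortC(unique(x@records$gene))
})

#' @rdname nTermsPerGene
#' @export
setMethod("nTermsPerGene", "AnnotationSet", function(x) {
  p <- annotationPairs(x)
  tab <- table(p$gene)
  setNames(as.integer(tab), names(tab))
})

#' @rdname nGenesPerTerm
#' @export
setMethod("nGenesPerTerm", "AnnotationSet", function(x) {
  p <- annotationPairs(x)
  tab <- table(p$term)
  setNames(as.integer(tab), names(tab))
})

#' @export
setMethod("show", "AnnotationSet", function(object) {
  p <- annotationPairs(object)
  cat(sprintf(
    "AnnotationSet: %d (term, gene) pairs over %d terms and %d genes\n",
    nrow(p), length(unique(p$term)), length(unique(p$gene))))
})
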