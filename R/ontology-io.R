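#' Parse an OBO ontology file into an IS_A DAG
#'
#' Reads an OBO 1.2/1.4 flat file and returns the IS_A DAG over its
#' non-obsolete `[Term]` stanzas. Only the keys `id`, `name`, `namespace`,
#' `is_a`, `is_obsolete` and `alt_id` are interpreted; `relationship:` lines
#' (part_of and friends) are ignored with a warning counting how many were
#' skipped, and other stanza types (`[Typedef]`, ...) are skipped entirely.
#' IS_A edges pointing at obsolete or undeclared terms are dropped with a
#' warning. A cyclic IS_A graph is rejected.
#'
#' @param path path to an OBO file.
#' @return an [Ontology-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:1", "name: root", "",
#'              "[Term]", "id: T:2", "name: leaf", "is_a: T:1 ! root"), obo)
#' ont <- parseOBO(obo)
#' terms(ont)
#' ancestors(ont, "T:2")
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) .stopf("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\r$", "", lines)

  # stanza boundaries
  stanzaStart <- grep("^\\[[^]]+\\]\\s*$", lines)
  skippedRel <- 0L

  ids <- character(); nms <- character(); nsp <- character()
  obsolete <- logical()
  edgeChild <- character(); edgeParent <- character()
  altFrom <- character(); altTo <- character()

  if (length(stanzaStart)) {
    stanzaEnd <- c(stanzaStart[-1L] - 1L, length(lines))
    for (s in seq_along(stanzaStart)) {
      header <- trimws(lines[[stanzaStart[[s]]]])
      if (header != "[Term]") next
      body <- lines[seq(stanzaStart[[s]] + 1L, length.out =
                          max(0L, stanzaEnd[[s]] - stanzaStart[[s]]))]
      body <- body[nzchar(trimws(body))]
      keyed <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
      bad <- which(vapply(keyed, length, 1L) != 3L)
      if (length(bad))
        .stopf("malformed OBO stanza line %d: '%s'",
               stanzaStart[[s]] + bad[[1L]], body[[bad[[1L]]]])
      keys <- vapply(keyed, `[[`, "", 2L)
      vals <- trimws(vapply(keyed, `[[`, "", 3L))
      id <- vals[keys == "id"]
      if (length(id) != 1L)
        .stopf("OBO [Term] stanza at line %d lacks a unique 'id:' line",
               stanzaStart[[s]])
      ids <- c(ids, id)
      nm <- vals[keys == "name"]
      nms <- c(nms, if (length(nm)) nm[[1L]] else "")
      ns <- vals[keys == "namespace"]
      nsp <- c(nsp, if (length(ns)) ns[[1L]] else "")
      obsolete <- c(obsolete,
                    any(keys == "is_obsolete" &
                        tolower(vals) %in% c("true", "yes")))
      isa <- vals[keys == "is_a"]
      if (length(isa)) {
        # strip the trailing "! name" comment
        tgt <- trimws(sub("!.*$", "", isa))
        edgeChild <- c(edgeChild, rep(id, length(tgt)))
        edgeParent <- c(edgeParent, tgt)
      }
      alt <- vals[keys == "alt_id"]
      if (length(alt)) {
        altFrom <- c(altFrom, alt)
        altTo <- c(altTo, rep(id, length(alt)))
      }
      skippedRel <- skippedRel + sum(keys == "relationship")
    }
  }

  if (anyDuplicated(ids))
    .stopf("duplicate term id(s) in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- !obsolete
  liveTerms <- ids[keep]
  liveNames <- setNames(nms[keep], liveTerms)
  liveNs <- setNames(nsp[keep], liveTerms)

  edgeOk <- edgeChild %in% liveTerms & edgeParent %in% liveTerms
  if (any(!edgeOk))
    .warnf("dropped %d IS_A edge(s) with obsolete or undeclared endpoints",
           sum(!edgeOk))
  edges <- unique(.df(child = edgeChild[edgeOk], parent = edgeParent[edgeOk]))
  if (skippedRel > 0L)
    .warnf("ignored %d non-IS_A relationship line(s)", skippedRel)

  cyc <- .findCycle(liveTerms, edges)
  if (!is.null(cyc))
    .stopf("cyclic IS_A graph in %s: %s", path, paste(cyc, collapse = " -> "))

  alt <- setNames(altTo, altFrom)
  alt <- alt[alt %in% liveTerms & !(names(alt) %in% liveTerms)]

  new("Ontology", terms = liveTerms, termNames = liveNames,
      termNamespace = liveNs, edges = edges, altIds = alt,
      source = as.character(path))
}

#' Write an ontology back to OBO format
#'
#' Emits one `[Term]` stanza per term (id, name, namespace, is_a lines),
#' terms sorted by identifier, so output is canonical: re-parsing yields
#' identical term and edge sets.
#'
#' @param ontology an [Ontology-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(ontology, path) {
  stopifnot(is(ontology, "Ontology"))
  parentsOf <- split(ontology@edges$parent, ontology@edges$child)
  out <- c("format-version: 1.2", "")
  for (t in .sortC(ontology@terms)) {
    out <- c(out, "[Term]", paste0("id: ", t))
    nm <- ontology@termNames[[t]]
    if (nzchar(nm)) out <- c(out, paste0("name: ", nm))
    ns <- ontology@termNamespace[[t]]
    if (nzchar(ns)) out <- c(out, paste0("namespace: ", ns))
    for (p in .sortC(parentsOf[[t]])) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @describeIn parseOBO term identifiers of the ontology.
#' @param x an [Ontology-class].
#' @param ... ignored.
#' @export
setMethod("terms", "Ontology", function(x, ...) x@terms)

#' @rdname roots
#' @export
setMethod("roots", "Ontology", function(ontology) {
  setdiff(ontology@terms, unique(ontology@edges$child))
})

#' @rdname isaEdges
#' @export
setMethod("isaEdges", "Ontology", function(ontology) ontology@edges)

#' @rdname ancestors
#' @export
setMethod("ancestors", "Ontology", function(ontology, term) {
  if (!term %in% ontology@terms) .stopf("unknown term: %s", term)
  parentsOf <- split(ontology@edges$parent, ontology@edges$child)
  seen <- character()
  frontier <- parentsOf[[term]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unlist(parentsOf[frontier], use.names = FALSE)
  }
  seen
})

# Ancestor sets for every term at once (memoized walk in topological order).
.ancestorClosure <- function(ontology) {
  termsv <- ontology@terms
  parentsOf <- split(ontology@edges$parent,
                     factor(ontology@edges$child, levels = termsv))
  anc <- vector("list", length(termsv))
  names(anc) <- termsv
  done <- setNames(rep(FALSE, length(termsv)), termsv)
  visit <- function(t) {
    stack <- t
    while (length(stack)) {
      u <- stack[[length(stack)]]
      ps <- parentsOf[[u]]
      pending <- ps[!done[ps]]
      if (length(pending)) {
        stack <- c(stack, pending[[1L]])
      } else {
        anc[[u]] <<- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
        done[[u]] <<- TRUE
        stack <- stack[-length(stack)]
        stack <- stack[!done[stack]]
      }
    }
  }
  for (t in termsv) if (!done[[t]]) visit(t)
  anc
}

#' @export
setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology with %d terms, %d IS_A edges, %d root(s)\n",
              length(object@terms), nrow(object@edges),
              length(roots(object))))
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
})
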