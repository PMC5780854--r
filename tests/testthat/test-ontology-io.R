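test_that("parseOBO reads terms, IS_A edges and roots from stanzas", {
  edges <- data.frame(child = c("T:B", "T:C"), parent = c("T:A", "T:A"),
                      stringsAsFactors = FALSE)
  path <- writeTempOBO(oboText(c("T:A", "T:B", "T:C"), edges))
  ont <- parseOBO(path)
  expect_setequal(terms(ont), c("T:A", "T:B", "T:C"))
  expect_equal(nrow(isaEdges(ont)), 2L)
  expect_equal(roots(ont), "T:A")
})

test_that("obsolete terms are dropped and alt_ids mapped to primary ids", {
  stanzas <- c("[Term]", "id: T:A", "name: alive", "alt_id: T:OLD", "",
               "[Term]", "id: T:B", "is_a: T:A", "",
               "[Term]", "id: T:DEAD", "is_obsolete: true", "")
  ont <- parseOBO(writeTempOBO(stanzas))
  expect_setequal(terms(ont), c("T:A", "T:B"))
  expect_false("T:DEAD" %in% terms(ont))
  expect_equal(ont@altIds[["T:OLD"]], "T:A")
})

test_that("non-IS_A relationship lines are ignored with a count", {
  stanzas <- c("[Term]", "id: T:A", "",
               "[Term]", "id: T:B", "is_a: T:A",
               "relationship: part_of T:A", "")
  expect_warning(ont <- parseOBO(writeTempOBO(stanzas)),
                 "1 non-IS_A relationship")
  expect_equal(nrow(isaEdges(ont)), 1L)
})

test_that("a complex-hierarchy fragment yields the child-to-parent edge", {
  stanzas <- c("[Term]", "id: GO:1902494", "name: catalytic complex",
               "is_a: GO:0032991 ! protein complex", "",
               "[Term]", "id: GO:0032991", "name: protein complex", "")
  ont <- parseOBO(writeTempOBO(stanzas))
  ed <- isaEdges(ont)
  expect_equal(ed$child, "GO:1902494")
  expect_equal(ed$parent, "GO:0032991")
})

test_that("cyclic IS_A graphs are rejected with a cycle report", {
  edges <- data.frame(child = c("T:A", "T:B", "T:C"),
                      parent = c("T:B", "T:C", "T:A"),
                      stringsAsFactors = FALSE)
  path <- writeTempOBO(oboText(c("T:A", "T:B", "T:C"), edges))
  expect_error(parseOBO(path), "cyclic IS_A graph")
})

test_that("malformed stanza lines are reported with their line number", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:A", "this is not a key-value line"), path)
  expect_error(parseOBO(path), "malformed OBO stanza line 3")
})

test_that("ancestors handles chains, roots and diamonds", {
  # chain C is_a B is_a A
  chain <- parseOBO(writeTempOBO(oboText(
    c("T:A", "T:B", "T:C"),
    data.frame(child = c("T:B", "T:C"), parent = c("T:A", "T:B"),
               stringsAsFactors = FALSE))))
  expect_setequal(ancestors(chain, "T:C"), c("T:B", "T:A"))
  expect_length(ancestors(chain, "T:A"), 0L)

  # diamond: D is_a B, D is_a C, B is_a A, C is_a A
  diamond <- parseOBO(writeTempOBO(oboText(
    c("T:A", "T:B", "T:C", "T:D"),
    data.frame(child = c("T:D", "T:D", "T:B", "T:C"),
               parent = c("T:B", "T:C", "T:A", "T:A"),
               stringsAsFactors = FALSE))))
  got <- ancestors(diamond, "T:D")
  expect_setequal(got, c("T:B", "T:C", "T:A"))
  expect_false(anyDuplicated(got) > 0)
  expect_error(ancestors(diamond, "T:missing"), "unknown term")
})

test_that("ancestors agrees with igraph reachability on random DAGs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12L
    ids <- sprintf("T:%02d", 1:n)
    child <- character(); parent <- character()
    for (i in 2:n) {
      k <- sample.int(min(i - 1L, 3L), 1L)
      ps <- sample.int(i - 1L, k)
      child <- c(child, rep(ids[i], k)); parent <- c(parent, ids[ps])
    }
    ont <- parseOBO(writeTempOBO(oboText(
      ids, data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = child, to = parent), vertices = ids)
    for (t in ids) {
      reach <- names(igraph::subcomponent(g, t, mode = "out"))
      expect_setequal(ancestors(ont, t), setdiff(reach, t))
      expect_false(t %in% ancestors(ont, t))
      expect_lt(length(ancestors(ont, t)), n)
    }
  }
})

test_that("ancestor sets are monotone under IS_A edge addition", {
  ids <- c("T:A", "T:B", "T:C", "T:D")
  base <- data.frame(child = c("T:B", "T:C"), parent = c("T:A", "T:A"),
                     stringsAsFactors = FALSE)
  more <- rbind(base, data.frame(child = "T:D", parent = "T:B"))
  ontBase <- parseOBO(writeTempOBO(oboText(ids, base)))
  ontMore <- parseOBO(writeTempOBO(oboText(ids, more)))
  for (t in ids)
    expect_true(all(ancestors(ontBase, t) %in% ancestors(ontMore, t)))
})

test_that("write/parse round trip preserves term and edge sets", {
  fx <- generateSynthetic(syntheticSpec(nTermsA = 15L, nTermsB = 8L,
                                        nGenes = 40L, nPlantedPairs = 2L,
                                        seed = 3L))
  ont <- fx$ontologyA
  out <- tempfile(fileext = ".obo")
  writeOBO(ont, out)
  ont2 <- parseOBO(out)
  expect_setequal(terms(ont2), terms(ont))
  e1 <- isaEdges(ont); e2 <- isaEdges(ont2)
  expect_setequal(paste(e1$child, e1$parent), paste(e2$child, e2$parent))
})
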