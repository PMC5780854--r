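test_that("parseGAF filters evidence codes and NOT qualifiers, dedups", {
  rec <- data.frame(
    gene = c("g1", "g2", "g3"),
    term = c("T:1", "T:1", "T:2"),
    evidence = c("EXP", "IEA", "IDA"),
    stringsAsFactors = FALSE)
  ann <- parseGAF(writeTempGAF(rec))
  expect_equal(nrow(annotationPairs(ann)), 2L)  # IEA record dropped

  # NOT-qualified records are dropped
  rec2 <- data.frame(gene = c("g1", "g2"), term = c("T:1", "T:1"),
                     evidence = c("EXP", "EXP"),
                     qualifier = c("", "NOT"), stringsAsFactors = FALSE)
  expect_equal(nrow(annotationPairs(parseGAF(writeTempGAF(rec2)))), 1L)

  # same (term, gene) from two references collapses to one pair
  rec3 <- data.frame(gene = c("g1", "g1"), term = c("T:1", "T:1"),
                     evidence = c("EXP", "EXP"), stringsAsFactors = FALSE)
  expect_equal(nrow(annotationPairs(parseGAF(writeTempGAF(rec3)))), 1L)
})

test_that("incidence counts N_T, N_G, n_j, n_g come from distinct ids", {
  rec <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g1"),
    term = c("T:1", "T:2", "T:1", "T:3", "T:3"),
    evidence = "EXP", stringsAsFactors = FALSE)
  ann <- parseGAF(writeTempGAF(rec), excludeEvidence = character())
  expect_length(terms(ann), 3L)      # N_T = 3
  expect_length(genes(ann), 2L)      # N_G = 2
  expect_equal(nTermsPerGene(ann)[["g1"]], 3L)
  expect_equal(nGenesPerTerm(ann)[["T:1"]], 2L)
})

test_that("wrong column counts raise a parse error naming the line", {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", "only\tthree\tcolumns"), path)
  expect_error(parseGAF(path), "line 2")
})

test_that("propagation closes annotation sets over ancestors exactly once", {
  chain <- parseOBO(writeTempOBO(oboText(
    c("T:A", "T:B", "T:C"),
    data.frame(child = c("T:B", "T:C"), parent = c("T:A", "T:B"),
               stringsAsFactors = FALSE))))
  ann <- parseGAF(writeTempGAF(data.frame(
    gene = "g1", term = "T:C", evidence = "EXP", stringsAsFactors = FALSE)))
  prop <- propagateAnnotations(ann, chain)
  expect_setequal(annotationPairs(prop)$term, c("T:A", "T:B", "T:C"))

  # a root annotation is unchanged
  annRoot <- parseGAF(writeTempGAF(data.frame(
    gene = "g1", term = "T:A", evidence = "EXP", stringsAsFactors = FALSE)))
  expect_equal(annotationPairs(propagateAnnotations(annRoot, chain)),
               annotationPairs(annRoot))

  # diamond: the apex gains the gene once despite two paths
  diamond <- parseOBO(writeTempOBO(oboText(
    c("T:A", "T:B", "T:C", "T:D"),
    data.frame(child = c("T:D", "T:D", "T:B", "T:C"),
               parent = c("T:B", "T:C", "T:A", "T:A"),
               stringsAsFactors = FALSE))))
  annD <- parseGAF(writeTempGAF(data.frame(
    gene = "g1", term = "T:D", evidence = "EXP", stringsAsFactors = FALSE)))
  p <- annotationPairs(propagateAnnotations(annD, diamond))
  expect_equal(sum(p$term == "T:A"), 1L)
  expect_setequal(p$term, c("T:A", "T:B", "T:C", "T:D"))
})

test_that("unknown annotation terms are reported and dropped", {
  chain <- parseOBO(writeTempOBO(oboText(
    c("T:A"), data.frame(child = character(), parent = character(),
                         stringsAsFactors = FALSE))))
  ann <- parseGAF(writeTempGAF(data.frame(
    gene = c("g1", "g2"), term = c("T:A", "T:GONE"), evidence = "EXP",
    stringsAsFactors = FALSE)))
  expect_message(prop <- propagateAnnotations(ann, chain), "dropping 1")
  expect_equal(annotationPairs(prop)$term, "T:A")
})

test_that("propagation is idempotent and parents cover their children", {
  fx <- generateSynthetic(syntheticSpec(nTermsA = 20L, nTermsB = 10L,
                                        nGenes = 50L, nPlantedPairs = 3L,
                                        seed = 5L))
  onts <- list(fx$ontologyA, fx$ontologyB)
  p1 <- propagateAnnotations(fx$annotations, onts)
  p2 <- propagateAnnotations(p1, onts)
  expect_identical(p1@records, p2@records)

  pairs <- annotationPairs(p1)
  geneSets <- split(pairs$gene, pairs$term)
  for (ont in onts) {
    ed <- isaEdges(ont)
    for (k in seq_len(nrow(ed))) {
      childGenes <- geneSets[[ed$child[k]]]
      if (is.null(childGenes)) next
      expect_true(all(childGenes %in% geneSets[[ed$parent[k]]]),
                  info = paste(ed$child[k], "->", ed$parent[k]))
    }
  }
})

test_that("evidence filtering commutes with propagation", {
  fx <- generateSynthetic(syntheticSpec(nTermsA = 12L, nTermsB = 12L,
                                        nGenes = 40L, nPlantedPairs = 2L,
                                        seed = 9L))
  onts <- list(fx$ontologyA, fx$ontologyB)
  raw <- parseGAF(fx$files[["gaf"]], excludeEvidence = character())
  a <- propagateAnnotations(filterEvidence(raw, "IEA"), onts)
  b <- filterEvidence(propagateAnnotations(raw, onts), "IEA")
  expect_identical(a@records, b@records)
})
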