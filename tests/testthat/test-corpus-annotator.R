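# Dictionary building, granularization and deterministic mention tagging.

test_that("dictionary build: surface lookup, case folding, collisions", {
  empty <- buildGeneDictionary(data.frame())
  expect_equal(length(empty), 0L)
  expect_equal(nrow(mentions(annotateDocument("d", "any text", empty))), 0L)

  # case-folded synonym and symbol of the same gene collapse to one key
  d <- buildGeneDictionary(data.frame(
    locus_tag = "dde_0526", symbol = "DsrA", synonyms = "dsrA",
    product = "x", pathway = "sulfur metabolism", go_terms = "GO:0018551:F"))
  expect_equal(sum(names(surfaceLookup(d)) == "dsra"), 1L)

  # one surface claimed by two genes is an ambiguity
  expect_error(buildGeneDictionary(data.frame(
    locus_tag = c("dde_0001", "dde_0002"), symbol = c("sat", "Sat"),
    synonyms = "", product = "p", pathway = "x", go_terms = "")),
    "ambiguous")

  fx <- loadFixtures()
  expect_equal(length(fx$dictionary), 20L)
  expect_gte(length(surfaceLookup(fx$dictionary)), 20L)
})

test_that("granularize covers the text with exact overlap bookkeeping", {
  txt <- strrep("ab cd ", 200)  # 1200 chars
  segs <- granularize(substr(txt, 1, 1000), window = 400, overlap = 100)
  expect_equal(segs$offset, c(0L, 300L, 600L))
  expect_equal(nchar(segs$text), c(400L, 400L, 400L))
  # a segment slices out of the source at its offset
  for (i in seq_len(nrow(segs)))
    expect_equal(segs$text[i],
                 substr(substr(txt, 1, 1000), segs$offset[i] + 1,
                        segs$offset[i] + nchar(segs$text[i])))

  expect_equal(nrow(granularize("", 10, 2)), 0L)
  short <- granularize("tiny", 10, 2)
  expect_equal(short$offset, 0L)
  expect_equal(short$text, "tiny")
  expect_error(granularize("abc", window = 5, overlap = 5), "overlap")
})

test_that("tagging is longest-match-leftmost at token boundaries", {
  fx <- loadFixtures()
  ac <- annotateDocument("d1", "The dsrA and sat genes", fx$dictionary)
  men <- mentions(ac)
  expect_equal(men$start, c(4L, 13L))
  expect_equal(men$end, c(8L, 16L))
  expect_equal(men$locus_tag, c("dde_0526", "dde_2265"))

  # no dictionary surface -> nothing tagged
  expect_equal(nrow(mentions(annotateDocument(
    "d2", "growth on molybdate media", fx$dictionary))), 0L)

  # a surface embedded in a longer word is not a token ("sat" in "sulfate")
  expect_equal(nrow(mentions(annotateDocument(
    "d3", "sulfate and satellite are not genes", fx$dictionary))), 0L)

  # longest-first resolution: "satB" must beat the prefix "sat"
  d <- buildGeneDictionary(data.frame(
    locus_tag = c("dde_0001", "dde_0002"), symbol = c("sat", "satB"),
    synonyms = "", product = "p", pathway = "x", go_terms = ""))
  m <- mentions(annotateDocument("d", "the satB gene", d))
  expect_equal(nrow(m), 1L)
  expect_equal(m$locus_tag, "dde_0002")
  expect_equal(m$text, "satB")
})

test_that("granularized annotation is equivalent to whole-text annotation", {
  cfg <- simulationConfig(seed = 21, n_docs = 6)
  d <- simulateGeneDictionary(cfg)
  sc <- simulateCorpus(d, cfg)
  doc <- documents(sc$corpus)
  # overlap always >= longest surface form - 1 so no span is split
  maxlen <- max(nchar(names(surfaceLookup(d))))
  for (w in c(40L, 75L, 131L)) {
    for (ov in c(maxlen, 25L)) {
      if (ov >= w) next
      for (i in seq_len(nrow(doc))) {
        whole <- mentions(annotateDocument(doc$doc_id[i], doc$text[i], d))
        gran <- mentions(annotateDocument(doc$doc_id[i], doc$text[i], d,
                                          window = w, overlap = ov))
        expect_identical(gran, whole)
      }
    }
  }
})

test_that("tagging is idempotent and independent of document order", {
  cfg <- simulationConfig(seed = 22, n_docs = 6)
  d <- simulateGeneDictionary(cfg)
  corp <- simulateCorpus(d, cfg)$corpus
  p1 <- annotateCorpus(corp, d)
  p2 <- annotateCorpus(p1, d)
  expect_identical(mentions(p1), mentions(p2))

  rev_corp <- new("AnnotatedCorpus",
                  documents = documents(corp)[rev(seq_len(nrow(documents(corp)))), ],
                  mentions = mentions(corp))
  p3 <- annotateCorpus(rev_corp, d)
  m1 <- mentions(p1); m3 <- mentions(p3)
  ord <- function(m) {
    m <- m[order(m$doc_id, m$start), ]; rownames(m) <- NULL; m
  }
  expect_identical(ord(m1), ord(m3))
})

test_that("recognized gene lists deduplicate per document", {
  expect_equal(recognizeGenes(new("AnnotatedCorpus",
    documents = data.frame(doc_id = character(), text = character()),
    mentions = essMiner:::emptyMentions()))$total_mentions, 0L)

  fx <- loadFixtures()
  txt <- "sat sat dsrA sat upp modA dsrA sat upp sat"
  ac <- annotateDocument("d1", txt, fx$dictionary)
  expect_equal(nrow(mentions(ac)), 10L)
  rg <- recognizeGenes(ac)
  expect_equal(length(rg$per_document$d1), 4L)
  expect_equal(rg$total_mentions, 10L)
  expect_equal(rg$unique_genes, 4L)
  expect_gte(rg$total_mentions, rg$unique_genes)
})

test_that("JSONL corpus round-trips exactly", {
  cfg <- simulationConfig(seed = 23, n_docs = 5)
  d <- simulateGeneDictionary(cfg)
  corp <- simulateCorpus(d, cfg)$corpus
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeCorpusJsonl(corp, f)
  back <- readCorpusJsonl(f)
  expect_identical(documents(back), documents(corp))
  m1 <- mentions(corp); m2 <- mentions(back)
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m2, m1)
})
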