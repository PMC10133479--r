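# Network loading, BFS expansion, enrichment test, pathway clustering.

test_that("edge table loading: merging, thresholding, validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("node_a", "node_b", "combined_score", "textmining_score",
                   "experimental_score", sep = "\t"), f)
  empty <- readInteractionNetwork(f)
  expect_equal(igraph::vcount(asIgraph(empty)), 0L)

  # duplicate pair keeps the max combined score
  writeLines(c("node_a\tnode_b\tcombined_score\ttextmining_score\texperimental_score",
               "a\tb\t0.5\t0.1\t0.2", "b\ta\t0.9\t0.3\t0.4"), f)
  net <- readInteractionNetwork(f)
  g <- asIgraph(net)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$combined_score, 0.9)

  # out-of-range score names the offending line
  writeLines(c("node_a\tnode_b\tcombined_score\ttextmining_score\texperimental_score",
               "a\tb\t1.2\t0.3\t0.4"), f)
  expect_error(readInteractionNetwork(f), "line 2")

  # rows below the threshold are dropped
  writeLines(c("node_a\tnode_b\tcombined_score\ttextmining_score\texperimental_score",
               "a\tb\t0.30\t0.3\t0.4", "b\tc\t0.80\t0.3\t0.4"), f)
  expect_equal(igraph::ecount(asIgraph(readInteractionNetwork(f))), 1L)
})

test_that("seed expansion is a depth-limited BFS over confident edges", {
  path5 <- mkNet(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")))
  expect_equal(expandSeeds(path5, "a", levels = 2), c("a", "b", "c"))
  expect_equal(expandSeeds(path5, "a", levels = 0), "a")
  # an isolated / absent seed is kept with a warning
  expect_warning(out <- expandSeeds(path5, "zzz", levels = 2), "absent")
  expect_equal(out, "zzz")

  # monotone in levels and in decreasing min_score
  net <- mkNet(cbind(c("a", "b", "c", "a"), c("b", "c", "d", "e")),
               score = c(0.9, 0.5, 0.9, 0.45))
  prev <- character()
  for (lv in 0:3) {
    cur <- expandSeeds(net, "a", levels = lv, min_score = 0.4)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  hi <- expandSeeds(net, "a", levels = 3, min_score = 0.8)
  lo <- expandSeeds(net, "a", levels = 3, min_score = 0.4)
  expect_true(all(hi %in% lo))
})

test_that("analytic enrichment p-value: degenerate and saturated sets", {
  k5 <- mkNet(t(utils::combn(paste0("k", 1:5), 2)))
  one <- enrichmentPvalue(k5, "k1")
  expect_equal(one$e_obs, 0L)
  expect_equal(one$p_value, 1)

  sat <- enrichmentPvalue(k5, paste0("k", 1:5))
  expect_equal(sat$e_obs, choose(5, 2))
  expect_true(sat$p_value >= 0 && sat$p_value <= 1)

  lonely <- buildInteractionNetwork(
    data.frame(node_a = character(), node_b = character(),
               combined_score = numeric(), textmining_score = numeric(),
               experimental_score = numeric()), nodes = c("a", "b"))
  expect_error(enrichmentPvalue(lonely, "a"), "no edges")
})

test_that("analytic p agrees with exhaustive enumeration on small fixtures", {
  fixtures <- list(
    # triangle + path + bridge; a non-clique triple
    list(net = mkNet(cbind(c("a", "a", "b", "d", "e", "c"),
                           c("b", "c", "c", "e", "f", "d"))),
         set = c("d", "e", "f")),
    # two bridged triangles; the triangle triple and a mixed triple
    list(net = mkNet(cbind(c("a", "a", "b", "d", "d", "e", "c"),
                           c("b", "c", "c", "e", "f", "f", "d"))),
         set = c("a", "b", "c")),
    list(net = mkNet(cbind(c("a", "a", "b", "d", "d", "e", "c"),
                           c("b", "c", "c", "e", "f", "f", "d"))),
         set = c("a", "b", "d")),
    # star: hub pair vs leaf triple
    list(net = mkNet(cbind(rep("h", 5), paste0("x", 1:5))),
         set = c("h", "x1", "x2")),
    # 10-ring with a half-connected quadruple
    list(net = mkNet(cbind(paste0("v", 1:10), paste0("v", c(2:10, 1)))),
         set = paste0("v", c(1, 2, 3, 7))),
    # 12-node: two bridged triangles + attached 5-ring
    list(net = mkNet(rbind(cbind(c("a", "a", "b", "d", "d", "e", "c"),
                                 c("b", "c", "c", "e", "f", "f", "d")),
                           cbind(c("f", "r1", "r2", "r3", "r4", "r5"),
                                 c("r1", "r2", "r3", "r4", "r5", "f")))),
         set = c("r1", "r2", "r3")))
  for (fx in fixtures) {
    a <- enrichmentPvalue(fx$net, fx$set)$p_value
    e <- enumPvalue(fx$net, fx$set)
    expect_true(a >= 0 && a <= 1)
    expect_gte(a, e / 2)
    expect_lte(a, e * 2)
  }
})

test_that("permutation p-value matches enumeration and is reproducible", {
  net <- mkNet(cbind(c("a", "a", "b", "d", "d", "e", "c"),
                     c("b", "c", "c", "e", "f", "f", "d")))
  p1 <- enrichmentPvaluePermutation(net, c("a", "b", "c"), n_perm = 5000,
                                    seed = 3)
  p2 <- enrichmentPvaluePermutation(net, c("a", "b", "c"), n_perm = 5000,
                                    seed = 3)
  expect_identical(p1$p_value, p2$p_value)
  ptrue <- enumPvalue(net, c("a", "b", "c"))
  se <- sqrt(ptrue * (1 - ptrue) / 5000)
  expect_lt(abs(p1$p_value - ptrue), 3 * se + 1 / 5001)

  # e_obs = 0 saturates at p = 1 under the add-one convention
  iso <- mkNet(cbind(c("a", "b"), c("b", "c")))
  p0 <- enrichmentPvaluePermutation(iso, c("a", "c"), n_perm = 200, seed = 1)
  expect_equal(p0$p_value, 1)
})

test_that("expected edge count is the mean of its own degree-model null", {
  cfg <- simulationConfig(seed = 11, n_genes = 40, pathway_quotas = NULL)
  d <- simulateGeneDictionary(cfg)
  net <- simulatePpiNetwork(d, cfg)
  g <- asIgraph(net)
  S <- geneRecords(d)$locus_tag[1:8]
  st <- essMiner:::edgeStatistics(g, S)
  deg <- igraph::degree(g, v = S)
  m <- igraph::ecount(g)
  pmat <- pmin(outer(deg, deg) / (2 * m), 1)
  pv <- pmat[upper.tri(pmat)]
  set.seed(5)
  draws <- replicate(4000, sum(runif(length(pv)) < pv))
  se <- sd(draws) / sqrt(4000)
  expect_lt(abs(mean(draws) - st$e_exp), 3 * se)
})

test_that("pathway clustering finds bridging genes", {
  # single-pathway subgraph: nobody bridges
  tri <- mkNet(cbind(c("a", "a", "b"), c("b", "c", "c")))
  cl <- clusterByPathway(tri, c("a", "b", "c"),
                         pathway = c(a = "p1", b = "p1", c = "p1"))
  expect_equal(cl$max_bridging_degree, 0L)
  expect_equal(length(cl$bridging_genes), 0L)

  # star center wired into three clusters bridges all three
  star <- mkNet(cbind(rep("hub", 3), c("s1", "s2", "s3")))
  cl2 <- clusterByPathway(star, c("hub", "s1", "s2", "s3"),
                          pathway = c(hub = "p0", s1 = "p1", s2 = "p2",
                                      s3 = "p3"))
  expect_equal(cl2$bridging_genes, "hub")
  expect_equal(cl2$max_bridging_degree, 3L)
})

test_that("network writers round-trip edges and export GraphML", {
  cfg <- simulationConfig(seed = 12)
  d <- simulateGeneDictionary(cfg)
  net <- simulatePpiNetwork(d, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeInteractionNetwork(net, f)
  back <- readInteractionNetwork(f, min_score = 0)
  expect_equal(igraph::ecount(asIgraph(back)), igraph::ecount(asIgraph(net)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeGraphml(net, gml)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(reread), igraph::ecount(asIgraph(net)))
  expect_true("pathway" %in% igraph::vertex_attr_names(reread))
})
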