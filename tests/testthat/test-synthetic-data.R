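# Synthetic-data generators: structure, planted statistics, determinism.

test_that("simulated dictionary honours size, quotas, locus-tag pattern", {
  cfg <- simulationConfig(seed = 2)
  d <- simulateGeneDictionary(cfg)
  rec <- geneRecords(d)
  expect_equal(nrow(rec), 20L)
  expect_true(all(grepl("^dde_[0-9]{4}$", rec$locus_tag)))
  expect_true(all(nzchar(rec$symbol)))
  expect_true(all(nzchar(rec$go_terms)))
  census <- categorizePathways(rec)$census
  expect_equal(unname(census[essMiner:::pathwayLevels()]),
               c(8L, 1L, 1L, 3L, 5L, 2L))

  d1 <- simulateGeneDictionary(simulationConfig(seed = 7, n_genes = 1))
  expect_equal(length(d1), 1L)
  expect_match(locusTags(d1), "^dde_[0-9]{4}$")

  expect_error(simulationConfig(n_genes = 0), "positive")
  expect_error(simulationConfig(decoy_rate = 1.5), "\\[0, 1\\]")
})

test_that("same seed reproduces every artifact exactly", {
  cfg <- simulationConfig(seed = 5, n_docs = 8, n_families = 40,
                          n_genomes = 10)
  d1 <- simulateGeneDictionary(cfg); d2 <- simulateGeneDictionary(cfg)
  expect_identical(geneRecords(d1), geneRecords(d2))
  c1 <- simulateCorpus(d1, cfg); c2 <- simulateCorpus(d2, cfg)
  expect_identical(mentions(c1$corpus), mentions(c2$corpus))
  expect_identical(documents(c1$corpus), documents(c2$corpus))
  n1 <- simulatePpiNetwork(d1, cfg); n2 <- simulatePpiNetwork(d2, cfg)
  expect_identical(igraph::as_data_frame(asIgraph(n1)),
                   igraph::as_data_frame(asIgraph(n2)))
  p1 <- simulatePangenome(cfg); p2 <- simulatePangenome(cfg)
  expect_identical(paMatrix(p1$matrix), paMatrix(p2$matrix))
  expect_identical(contiguityEdges(p1$graph), contiguityEdges(p2$graph))
})

test_that("corpus: planted mention counts follow the Poisson rate", {
  cfg <- simulationConfig(seed = 4)  # 50 docs, rate 4
  d <- simulateGeneDictionary(cfg)
  sc <- simulateCorpus(d, cfg)
  total <- nrow(mentions(sc$corpus))
  expect_lt(abs(total - 50 * 4), 3 * sqrt(50 * 4))

  # degenerate rate: no mentions at all
  cfg0 <- simulationConfig(seed = 4, mention_rate = 0)
  expect_equal(nrow(mentions(simulateCorpus(d, cfg0)$corpus)), 0L)

  expect_error(simulateCorpus(buildGeneDictionary(data.frame()), cfg),
               "non-empty")
})

test_that("corpus: gold offsets slice back to the text; decoys not in dictionary", {
  cfg <- simulationConfig(seed = 9, n_docs = 15)
  d <- simulateGeneDictionary(cfg)
  sc <- simulateCorpus(d, cfg)
  men <- mentions(sc$corpus)
  doc <- documents(sc$corpus)
  txt <- doc$text[match(men$doc_id, doc$doc_id)]
  expect_identical(substr(txt, men$start + 1L, men$end), men$text)
  expect_true(length(sc$truth$decoys) > 0)
  expect_false(any(tolower(sc$truth$decoys) %in% names(surfaceLookup(d))))
})

test_that("PPI generator: extreme densities give pathway cliques; moments match", {
  d <- simulateGeneDictionary(simulationConfig(seed = 3))
  cfg1 <- simulationConfig(seed = 3, cluster_density = 1,
                           background_density = 0)
  net <- simulatePpiNetwork(d, cfg1)
  g <- asIgraph(net)
  comp <- igraph::components(g)
  # one clique per pathway (each pathway with >= 1 gene forms one component)
  expect_equal(comp$no, 6L)
  rec <- geneRecords(d)
  for (pw in unique(rec$pathway)) {
    memb <- rec$locus_tag[rec$pathway == pw]
    sub <- igraph::induced_subgraph(g, memb)
    expect_equal(igraph::ecount(sub), choose(length(memb), 2))
  }
  scores <- igraph::E(g)$combined_score
  expect_true(all(scores >= 0 & scores <= 1))

  cfg2 <- simulationConfig(seed = 6)
  net2 <- simulatePpiNetwork(d, cfg2)
  np <- table(rec$pathway)
  wp <- sum(choose(np, 2)); tot <- choose(nrow(rec), 2)
  mu <- wp * cfg2$cluster_density + (tot - wp) * cfg2$background_density
  v <- wp * cfg2$cluster_density * (1 - cfg2$cluster_density) +
    (tot - wp) * cfg2$background_density * (1 - cfg2$background_density)
  expect_lt(abs(igraph::ecount(asIgraph(net2)) - mu), 3 * sqrt(v))

  expect_error(simulationConfig(cluster_density = 1.7), "\\[0, 1\\]")
})

test_that("pangenome generator: planted component structure and moments", {
  # degenerate cloud: probability 0 -> all-zero rows
  spec0 <- list(
    list(label = "persistent", weight = 0.5, type = "uniform", p = 0.95),
    list(label = "cloud", weight = 0.5, type = "uniform", p = 0))
  cfg0 <- simulationConfig(seed = 2, n_families = 60, n_genomes = 12,
                           mixture_spec = spec0)
  pan0 <- simulatePangenome(cfg0)
  cl <- pan0$truth$component == "cloud"
  expect_true(any(cl))
  expect_true(all(rowSums(paMatrix(pan0$matrix)[cl, , drop = FALSE]) == 0))

  # persistent mean row-sum: p = 0.98 over 40 genomes -> 39.2
  cfg <- simulationConfig(seed = 8, n_genomes = 40)
  pan <- simulatePangenome(cfg)
  pr <- pan$truth$component == "persistent"
  rs <- rowSums(paMatrix(pan$matrix)[pr, , drop = FALSE])
  se <- sqrt(40 * 0.98 * 0.02 / sum(pr))
  expect_lt(abs(mean(rs) - 39.2), 3 * se)

  # empirical component frequencies approach the mixing weights
  cfgL <- simulationConfig(seed = 13, n_families = 2000, n_genomes = 10)
  panL <- simulatePangenome(cfgL)
  freq <- table(panL$truth$component) / 2000
  for (m in cfgL$mixture_spec) {
    se <- sqrt(m$weight * (1 - m$weight) / 2000)
    expect_lt(abs(freq[[m$label]] - m$weight), 3 * se)
  }

  # contiguity_prob 0 -> edgeless graph
  cfgE <- simulationConfig(seed = 2, n_families = 40, n_genomes = 8,
                           contiguity_prob = 0)
  expect_equal(nrow(contiguityEdges(simulatePangenome(cfgE)$graph)), 0L)

  # invalid mixture weights rejected
  badspec <- list(
    list(label = "a", weight = 0.6, type = "uniform", p = 0.9),
    list(label = "b", weight = 0.5, type = "uniform", p = 0.1))
  expect_error(simulationConfig(mixture_spec = badspec), "sum to 1")
})
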