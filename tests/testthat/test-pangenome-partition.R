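# Bernoulli mixture EM, MRF smoothing, partition labelling, query mapping.

test_that("EM degenerate cases and closed forms", {
  ones <- mkPa(list(rep(1L, 4), rep(1L, 4), rep(1L, 4)))
  fit <- fitBernoulliMixture(ones, K = 1, seed = 1)
  expect_true(all(presenceProfiles(fit$model) >= 1 - 1e-4 - 1e-12))
  expect_equal(mixingWeights(fit$model), 1)

  # K = 1 reduces to the (clamped) column-mean MLE
  pa <- mkPa(list(c(1L, 1L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L),
                  c(1L, 1L, 1L)))
  f1 <- fitBernoulliMixture(pa, K = 1, seed = 3)
  cm <- colMeans(paMatrix(pa))
  expect_equal(unname(presenceProfiles(f1$model)[1, ]),
               unname(pmin(pmax(cm, 1e-4), 1 - 1e-4)), tolerance = 1e-8)

  # perturbing theta away from the K = 1 MLE cannot raise the likelihood
  ll0 <- bmmLogLikelihood(pa, f1$model)
  for (d in c(-0.05, 0.05)) {
    m2 <- f1$model
    m2@theta <- pmin(pmax(m2@theta + d, 1e-4), 1 - 1e-4)
    expect_lte(bmmLogLikelihood(pa, m2), ll0 + 1e-12)
  }

  expect_error(fitBernoulliMixture(pa, K = 10, seed = 1), "exceeds")
})

test_that("log-likelihood: closed form, additivity, responsibilities", {
  pa <- mkPa(list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(0L, 0L)))
  m <- fitBernoulliMixture(pa, K = 1, seed = 1)$model
  m@theta[] <- 0.5
  expect_equal(bmmLogLikelihood(pa, m), 4 * 2 * log(0.5))

  # duplicating a family row adds exactly that row's contribution
  X <- paMatrix(pa)
  pa2 <- presenceAbsenceMatrix(rbind(X, f5 = X["f3", ]))
  lj <- essMiner:::componentLogJoint(X["f3", , drop = FALSE],
                                     mixingWeights(m), presenceProfiles(m))
  row_ll <- unname(essMiner:::logRowSumExp(lj))
  expect_equal(bmmLogLikelihood(pa2, m), bmmLogLikelihood(pa, m) + row_ll)

  fit <- fitBernoulliMixture(pa, K = 2, seed = 5)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$trace) >= -1e-9))

  # dimension mismatch is rejected
  pa3 <- mkPa(list(c(1L, 0L, 1L)))
  expect_error(bmmLogLikelihood(pa3, m), "mismatch")
})

test_that("genome column permutation permutes theta identically", {
  cfg <- simulationConfig(seed = 17, n_families = 60, n_genomes = 8)
  pan <- simulatePangenome(cfg)
  X <- paMatrix(pan$matrix)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  fitA <- fitBernoulliMixture(pan$matrix, K = 3, seed = 2)
  fitB <- fitBernoulliMixture(presenceAbsenceMatrix(X[, perm]), K = 3,
                              seed = 2)
  expect_equal(presenceProfiles(fitB$model),
               presenceProfiles(fitA$model)[, perm], tolerance = 1e-6)
  expect_equal(mixingWeights(fitB$model), mixingWeights(fitA$model),
               tolerance = 1e-6)
})

test_that("ICM smoothing: decoupled limit, edgeless graph, canonical flip", {
  fam <- icmFamily(betas = 0)
  inst <- fam[[2]]
  pa <- presenceAbsenceMatrix(inst$X)
  model <- mkModel()
  lj <- essMiner:::componentLogJoint(inst$X, mixingWeights(model),
                                     presenceProfiles(model))
  resp <- exp(lj - essMiner:::logRowSumExp(lj))
  fit <- list(model = model, responsibilities = resp)
  g <- contiguityGraph(data.frame(from = c("f1", "f2"), to = c("f2", "f3"),
                                  weight = 1), rownames(inst$X))
  # beta = 0 equals the responsibility argmax
  expect_equal(unname(smoothLabelsICM(pa, fit, g, beta = 0)),
               max.col(resp, ties.method = "first"))
  # an edgeless graph changes nothing for any beta
  g0 <- contiguityGraph(data.frame(from = character(), to = character(),
                                   weight = numeric()), rownames(inst$X))
  expect_equal(unname(smoothLabelsICM(pa, fit, g0, beta = 3)),
               max.col(resp, ties.method = "first"))

  # 3-family path: the middle family weakly prefers the mid component, both
  # neighbors strongly prefer the low one; sufficient coupling flips the
  # middle, matching exhaustive energy minimization over all 27 labelings
  G <- 6
  X <- rbind(f1 = rep(0L, G), f2 = c(rep(0L, 4), 1L, 1L), f3 = rep(0L, G))
  colnames(X) <- paste0("g", 1:G)
  paX <- presenceAbsenceMatrix(X)
  ljX <- essMiner:::componentLogJoint(X, mixingWeights(model),
                                      presenceProfiles(model))
  respX <- exp(ljX - essMiner:::logRowSumExp(ljX))
  fitX <- list(model = model, responsibilities = respX)
  gX <- contiguityGraph(data.frame(from = c("f1", "f2"), to = c("f2", "f3"),
                                   weight = 1), rownames(X))
  free <- smoothLabelsICM(paX, fitX, gX, beta = 0)
  expect_equal(unname(free), c(3, 2, 3))
  coupled <- smoothLabelsICM(paX, fitX, gX, beta = 2)
  expect_equal(unname(coupled), c(3, 3, 3))
  expect_equal(unname(coupled),
               unname(enumPotts(ljX, gX, beta = 2)$labels))
})

test_that("ICM matches exhaustive minimization across the instance family", {
  model <- mkModel()
  for (inst in icmFamily(betas = c(0, 0.8, 2.5))) {
    pa <- presenceAbsenceMatrix(inst$X)
    lj <- essMiner:::componentLogJoint(inst$X, mixingWeights(model),
                                       presenceProfiles(model))
    resp <- exp(lj - essMiner:::logRowSumExp(lj))
    g <- contiguityGraph(data.frame(from = c("f1", "f2"), to = c("f2", "f3"),
                                    weight = 1), rownames(inst$X))
    icm <- smoothLabelsICM(pa, list(model = model, responsibilities = resp),
                           g, beta = inst$beta)
    expect_equal(pottsEnergy(unname(icm), lj, g, inst$beta),
                 enumPotts(lj, g, inst$beta)$best, tolerance = 1e-12)
  }
})

test_that("ICM never degrades the Potts energy of the initial labelling", {
  model <- mkModel()
  set.seed(41)
  for (i in 1:25) {
    G <- 6
    X <- matrix(rbinom(3 * G, 1, runif(3 * G)), 3, G,
                dimnames = list(paste0("f", 1:3), paste0("g", 1:G)))
    pa <- presenceAbsenceMatrix(X)
    lj <- essMiner:::componentLogJoint(X, mixingWeights(model),
                                       presenceProfiles(model))
    resp <- exp(lj - essMiner:::logRowSumExp(lj))
    keep <- runif(3) < 0.7
    ed <- data.frame(from = c("f1", "f1", "f2"), to = c("f2", "f3", "f3"),
                     weight = 1)[keep, , drop = FALSE]
    g <- contiguityGraph(ed, rownames(X))
    beta <- runif(1, 0, 4)
    icm <- smoothLabelsICM(pa, list(model = model, responsibilities = resp),
                           g, beta = beta)
    init <- max.col(resp, ties.method = "first")
    expect_gte(pottsEnergy(unname(icm), lj, g, beta),
               pottsEnergy(init, lj, g, beta))
  }
})

test_that("partition labelling ranks components by mean presence", {
  cfg <- simulationConfig(seed = 19, n_families = 150, n_genomes = 30)
  pan <- simulatePangenome(cfg)
  fit <- fitBernoulliMixture(pan$matrix, K = 3, seed = 19)
  res <- assignPartitions(pan$matrix, fit)
  part <- partitions(res)
  X <- paMatrix(pan$matrix)
  # extreme rows land in the extreme partitions
  full <- rownames(X)[rowSums(X) == ncol(X)]
  rare <- rownames(X)[rowSums(X) == 1]
  if (length(full)) expect_true(all(part[full] == "persistent"))
  if (length(rare)) expect_true(all(part[rare] == "cloud"))
  # ranking by mean theta
  tbar <- rowMeans(presenceProfiles(res@model))
  labels <- componentLabels(res@model)
  expect_equal(labels[which.max(tbar)], "persistent")
  expect_equal(labels[which.min(tbar)], "cloud")
  expect_error(assignPartitions(pan$matrix,
                                fitBernoulliMixture(pan$matrix, K = 2,
                                                    seed = 1)),
               "K >= 3")
})

test_that("planted mixture is recovered by EM + ICM", {
  cfg <- simulationConfig(seed = 29, n_families = 300, n_genomes = 40)
  pan <- simulatePangenome(cfg)
  fit <- fitBernoulliMixture(pan$matrix, K = 3, seed = 29)
  comp <- smoothLabelsICM(pan$matrix, fit, pan$graph)
  res <- assignPartitions(pan$matrix, fit, component = comp)
  truth <- setNames(pan$truth$component, pan$truth$family)
  acc <- mean(partitions(res)[names(truth)] == truth)
  expect_gte(acc, 0.95)
})

test_that("query genes inherit their family's partition", {
  empty <- mapQueryGenes(data.frame(),
                         assignPartitions(mkPa(list(c(1L, 1L), c(0L, 1L),
                                                    c(0L, 0L))),
                                          fitBernoulliMixture(
                                            mkPa(list(c(1L, 1L), c(0L, 1L),
                                                      c(0L, 0L))),
                                            K = 3, seed = 1)))
  expect_equal(nrow(empty$table), 0L)

  pa <- mkPa(list(rep(1L, 6), rep(1L, 6), c(1L, 1L, 1L, 0L, 0L, 0L),
                  rep(0L, 6), c(0L, 0L, 0L, 0L, 0L, 1L)))
  fit <- fitBernoulliMixture(pa, K = 3, seed = 2)
  res <- assignPartitions(pa, fit)
  q <- data.frame(gene = c("gene1", "gene2", "ghost"),
                  family = c("f1", "f4", "nofam"),
                  pident = c(99.1, 87.5, 10), evalue = c(1e-50, 1e-20, 1),
                  bit_score = c(500, 210, 12))
  mq <- mapQueryGenes(q, res)
  expect_equal(nrow(mq$table), 2L)
  expect_equal(mq$table$partition[mq$table$gene == "gene1"],
               unname(partitions(res)["f1"]))
  expect_equal(mq$table$pident, c(99.1, 87.5))
  expect_equal(mq$unmatched$gene, "ghost")
})

test_that("presence/absence and partition files round-trip", {
  cfg <- simulationConfig(seed = 23, n_families = 50, n_genomes = 10,
                          mixture_spec = list(
                            list(label = "persistent", weight = 0.6,
                                 type = "uniform", p = 0.95),
                            list(label = "shell", weight = 0.25,
                                 type = "block", p_in = 0.9, p_out = 0.1,
                                 block_frac = 0.5),
                            list(label = "cloud", weight = 0.15,
                                 type = "uniform", p = 0.15)))
  pan <- simulatePangenome(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  writePresenceAbsence(pan$matrix, f)
  back <- suppressWarnings(readPresenceAbsence(f))
  keep <- rowSums(paMatrix(pan$matrix)) > 0
  expect_identical(paMatrix(back), paMatrix(pan$matrix)[keep, , drop = FALSE])

  fit <- fitBernoulliMixture(back, K = 3, seed = 4)
  res <- assignPartitions(back, fit)
  pf <- withr::local_tempfile(fileext = ".tsv")
  writePartitionResult(res, pf)
  tab <- read.delim(pf)
  expect_equal(nrow(tab), length(familyIds(back)))
  expect_true(all(abs(rowSums(tab[, c("responsibility_persistent",
                                      "responsibility_shell",
                                      "responsibility_cloud")]) - 1) < 1e-6))
  mf <- withr::local_tempfile(fileext = ".json")
  writeModelJson(res@model, mf)
  mj <- jsonlite::fromJSON(mf)
  expect_equal(mj$K, 3L)
  expect_equal(sum(mj$weights), 1, tolerance = 1e-9)
})
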