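# End-to-end pipeline orchestration, configuration and packaged fixtures.

#' Load the packaged study fixtures
#'
#' Returns the curated in-package fixtures used by the examples and the
#' reproduction tests:
#' \itemize{
#'   \item \code{dictionary}: the 20-gene curated annotation table for
#'     \emph{Oleidesulfovibrio alaskensis} G20 (locus tags, symbols,
#'     products, the six-pathway census 8/1/1/3/5/2, GO terms).  GO aspects
#'     and the synonym column are curated additions; composite printed gene
#'     names (e.g. hdrA/qmoA) are split into symbol + synonym.
#'   \item \code{partitions}: the 116-gene pathway x
#'     persistent/shell/cloud segregation table (grand totals 81/25/10).
#'   \item \code{mapped_path}, \code{symbols_path}, \code{network_path}:
#'     paths of the synthetic reconstructions of the mined-symbol funnel
#'     (91 symbols, 42 mapped, 20 retained) and of the enriched PPI
#'     subnetwork in which dde_2265 (sat) bridges all six pathway clusters.
#'     These three are synthetic stand-ins (the study's supplementary
#'     equivalents are not machine-published) and are named accordingly.
#' }
#'
#' @return A list with elements \code{dictionary}
#'   ([GeneDictionary-class]), \code{partitions} (\code{data.frame}),
#'   \code{mapped_path}, \code{symbols_path}, \code{network_path}.
#' @examples
#' fx <- loadFixtures()
#' nrow(fx$partitions)
#' @export
loadFixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "essMiner",
                                 mustWork = TRUE)
  list(dictionary = readGeneDictionary(ext("annotated_gene_dictionary.tsv")),
       partitions = utils::read.delim(ext("enriched_gene_partitions.tsv"),
                                      stringsAsFactors = FALSE),
       mapped_path = ext("mapped_genes_synthetic.tsv"),
       symbols_path = ext("mined_symbols_synthetic.txt"),
       network_path = ext("enriched_ppi_synthetic.tsv"))
}

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [runPipeline()].
#' Stages run in the order simulate, annotate, evaluate, map, enrich,
#' partition, report; any stage can be toggled off provided the inputs of
#' later stages are supplied as files.
#'
#' @param out_dir run directory (created).
#' @param seed non-negative integer master seed.
#' @param stages named logical vector toggling stages; missing names default
#'   to \code{TRUE}.
#' @param dictionary,corpus,network,matrix,graph,symbols,gene_partitions
#'   input file paths (filled in by the simulate stage when it runs).
#' @param sim a [simulationConfig()] for the simulate stage (its seed is
#'   overridden by \code{seed}).
#' @param levels,min_score enrichment expansion depth and score threshold.
#' @param K,beta,tol mixture components, MRF coupling and EM tolerance.
#' @param n_slices evaluation slices.
#' @param overrides essentiality-call override notes (named character).
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(out_dir, seed = 1L, stages = c(),
                           dictionary = NULL, corpus = NULL, network = NULL,
                           matrix = NULL, graph = NULL, symbols = NULL,
                           gene_partitions = NULL, sim = NULL,
                           levels = 2L, min_score = 0.4, K = 3L, beta = 2.5,
                           tol = 1e-6, n_slices = 5L, overrides = NULL) {
  stage_names <- c("simulate", "annotate", "evaluate", "map", "enrich",
                   "partition", "report")
  st <- setNames(rep(TRUE, length(stage_names)), stage_names)
  if (length(stages)) {
    bad <- setdiff(names(stages), stage_names)
    stopIfNot(length(bad) == 0,
              paste("unknown stage(s):", paste(bad, collapse = ", ")))
    st[names(stages)] <- as.logical(stages)
  }
  stopIfNot(is.numeric(seed) && length(seed) == 1L && seed >= 0,
            "seed must be a non-negative integer")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = st,
              dictionary = dictionary, corpus = corpus, network = network,
              matrix = matrix, graph = graph, symbols = symbols,
              gene_partitions = gene_partitions,
              sim = sim, levels = levels, min_score = min_score,
              K = as.integer(K), beta = beta, tol = tol,
              n_slices = as.integer(n_slices), overrides = overrides)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [pipelineConfig()] fields (\code{stages} as a
#'   name -> true/false map).
#' @param out_dir optional override of the configured output directory.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  if (!is.null(y$overrides)) y$overrides <- unlist(y$overrides)
  if (!is.null(y$sim)) y$sim <- do.call(simulationConfig, y$sim)
  do.call(pipelineConfig, y)
}

needFile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("stage input missing: %s (%s); run the producing stage or ",
                 what, if (is.null(path)) "no path configured" else path),
         "point the config at an existing file", call. = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the configured stages in order — simulate (write synthetic
#' inputs), annotate (dictionary tagging of the corpus), evaluate
#' (slice-based mention F1 against gold), map (symbol-to-genome funnel with
#' deduplication), enrich (seed expansion, enrichment p-value, pathway
#' clusters and bridging genes, GraphML export), partition (Bernoulli
#' mixture + EM + ICM smoothing), report (segregation table and
#' essentiality calls) — and writes a manifest recording the seed, the
#' stages run and an md5 digest of every artifact.  With a fixed seed two
#' runs produce byte-identical artifacts and manifests.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[essMiner] ", ...)
  st <- config$stages
  paths <- config[c("dictionary", "corpus", "network", "matrix", "graph",
                    "symbols", "gene_partitions")]
  produced <- character()

  if (st[["simulate"]]) {
    say("simulate: writing synthetic inputs")
    sim <- config$sim
    if (is.null(sim)) sim <- simulationConfig(seed = config$seed)
    sim$seed <- config$seed
    dict <- simulateGeneDictionary(sim)
    corp <- simulateCorpus(dict, sim)
    net <- simulatePpiNetwork(dict, sim)
    pan <- simulatePangenome(sim)
    idir <- file.path(out, "inputs")
    dir.create(idir, showWarnings = FALSE)
    paths$dictionary <- writeGeneDictionary(dict, file.path(idir, "dictionary.tsv"))
    paths$corpus <- writeCorpusJsonl(corp$corpus, file.path(idir, "corpus.jsonl"))
    paths$network <- writeInteractionNetwork(net, file.path(idir, "network.tsv"))
    paths$matrix <- writePresenceAbsence(pan$matrix, file.path(idir, "pa_matrix.csv"))
    paths$graph <- writeContiguityGraph(pan$graph, file.path(idir, "contiguity.tsv"))
    writeTruthLabels(pan$truth, file.path(idir, "truth_components.tsv"))
    produced <- c(produced, unlist(paths[c("dictionary", "corpus", "network",
                                           "matrix", "graph")]),
                  file.path(idir, "truth_components.tsv"))
  }

  dict <- NULL
  getDict <- function() {
    if (is.null(dict))
      dict <<- readGeneDictionary(needFile(paths$dictionary, "dictionary TSV"))
    dict
  }
  predicted <- NULL

  if (st[["annotate"]]) {
    say("annotate: tagging corpus with dictionary mentions")
    gold <- readCorpusJsonl(needFile(paths$corpus, "corpus JSONL"))
    predicted <- annotateCorpus(gold, getDict())
    p <- file.path(out, "annotated.jsonl")
    writeCorpusJsonl(predicted, p)
    produced <- c(produced, p)
  }

  if (st[["evaluate"]]) {
    say("evaluate: scoring predictions against gold mentions")
    gold <- readCorpusJsonl(needFile(paths$corpus, "corpus JSONL"))
    if (is.null(predicted))
      predicted <- readCorpusJsonl(needFile(file.path(out, "annotated.jsonl"),
                                            "annotated JSONL"))
    ns <- min(config$n_slices, nrow(documents(gold)))
    ev <- sliceEvaluate(gold, predicted, n_slices = ns, seed = config$seed)
    p <- file.path(out, "evaluation.json")
    writeEvalReport(ev, p)
    produced <- c(produced, p)
  }

  retained <- NULL
  if (st[["map"]]) {
    say("map: symbol-to-genome funnel")
    symbols <- if (!is.null(paths$symbols)) {
      readLines(needFile(paths$symbols, "symbol list"), warn = FALSE)
    } else if (!is.null(predicted)) {
      # fall back to the recognized genes of the annotated corpus
      unique(mentions(predicted)$text)
    } else stop("map stage needs a symbols file or an annotated corpus",
                call. = FALSE)
    symbols <- symbols[nzchar(trimws(symbols))]
    funnel <- deduplicateMapped(mapToGenome(symbols, getDict()))
    p <- file.path(out, "mapping_funnel.tsv")
    ret <- retainedGenes(funnel)
    rem <- removedGenes(funnel)
    tab <- rbind(cbind(ret, status = "retained", reason = ""),
                 cbind(rem[, names(ret)], status = "removed",
                       reason = rem$reason))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    produced <- c(produced, p)
    retained <- ret
  }

  enriched <- NULL
  if (st[["enrich"]]) {
    say("enrich: subnetwork expansion and enrichment test")
    rec <- geneRecords(getDict())
    net <- readInteractionNetwork(needFile(paths$network, "network TSV"),
                                  min_score = config$min_score,
                                  pathway = setNames(rec$pathway, rec$locus_tag))
    seeds <- if (!is.null(retained)) retained$locus_tag else rec$locus_tag
    enriched <- expandSeeds(net, seeds, levels = config$levels,
                            min_score = config$min_score)
    enr <- enrichmentPvalue(net, enriched)
    cl <- clusterByPathway(net, enriched)
    p1 <- file.path(out, "enrichment.json")
    jsonlite::write_json(list(seeds = seeds, enriched = enriched,
                              e_obs = enr$e_obs, e_exp = enr$e_exp,
                              p_value = enr$p_value,
                              bridging = cl$bridging,
                              bridging_genes = cl$bridging_genes),
                         p1, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    p2 <- file.path(out, "enriched_subnetwork.graphml")
    writeGraphml(net, p2, node_set = enriched)
    produced <- c(produced, p1, p2)
  }

  partition_result <- NULL
  if (st[["partition"]]) {
    say("partition: Bernoulli mixture EM + MRF smoothing")
    pa <- readPresenceAbsence(needFile(paths$matrix, "presence/absence CSV"))
    gr <- if (!is.null(paths$graph) && file.exists(paths$graph))
      readContiguityGraph(paths$graph, familyIds(pa)) else NULL
    fit <- fitBernoulliMixture(pa, K = config$K, tol = config$tol,
                               seed = config$seed, beta = config$beta)
    comp <- smoothLabelsICM(pa, fit, gr, beta = config$beta)
    partition_result <- assignPartitions(pa, fit, component = comp)
    p1 <- file.path(out, "partitions.tsv")
    writePartitionResult(partition_result, p1)
    p2 <- file.path(out, "model.json")
    writeModelJson(partition_result@model, p2)
    produced <- c(produced, p1, p2)
  }

  if (st[["report"]]) {
    say("report: segregation table and essentiality calls")
    gp <- if (!is.null(paths$gene_partitions)) {
      utils::read.delim(needFile(paths$gene_partitions, "gene partition TSV"),
                        stringsAsFactors = FALSE)
    } else if (!is.null(partition_result)) {
      # families whose id is a known locus tag inherit its pathway
      rec <- geneRecords(getDict())
      part <- partitions(partition_result)
      data.frame(gene = names(part),
                 pathway = rec$pathway[match(names(part), rec$locus_tag)],
                 partition = unname(part), stringsAsFactors = FALSE)
    } else stop("report stage needs gene_partitions or a partition run",
                call. = FALSE)
    seg <- segregatePartitions(gp)
    calls <- callEssentiality(gp, overrides = config$overrides)
    rp <- writeReport(seg, calls, file.path(out, "report"))
    produced <- c(produced, unname(rp))
  }

  produced <- unique(produced)
  manifest <- list(
    seed = config$seed,
    stages = as.list(st),
    parameters = list(levels = config$levels, min_score = config$min_score,
                      K = config$K, beta = config$beta, tol = config$tol,
                      n_slices = config$n_slices),
    inputs = lapply(Filter(Negate(is.null), paths), function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_),
    outputs = setNames(as.list(unname(tools::md5sum(produced))),
                       vapply(produced, function(p)
                         sub("^/+", "", sub(normalizePath(out), "", normalizePath(p),
                                            fixed = TRUE)), character(1))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(produced), " artifacts in ", out)
  invisible(manifest)
}
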