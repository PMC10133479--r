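# Synthetic-data generators: gene dictionary, literature corpus with planted
# mentions, clustered scored PPI network, and a planted-mixture pangenome
# with contiguity graph.  One master seed feeds an independent derived
# stream per generator, so sub-experiments are reproducible in isolation.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data module.  The
#' defaults emulate the study conditions the pipeline was designed around: a
#' 20-gene curated dictionary with pathway census (8, 1, 1, 3, 5, 2) over the
#' six pathways, a 50-document corpus averaging 4 planted mentions per
#' document with a 10\% decoy-token rate, a 6-pathway-clustered PPI network,
#' and a 63-genome pangenome drawn from a 3-component Bernoulli mixture
#' (persistent near 1, block-structured shell, cloud near 0) with component
#' proportions matching the observed persistent/shell/cloud split.
#'
#' @param seed master integer seed.
#' @param n_genes dictionary size (>= 1).
#' @param pathway_quotas optional integer vector over the six pathways
#'   summing to \code{n_genes}; \code{NULL} spreads genes near-evenly.
#' @param n_docs corpus size.
#' @param mention_rate mean planted mentions per document (Poisson).
#' @param decoy_rate fraction of filler tokens replaced by gene-like decoys
#'   absent from the dictionary.
#' @param n_families,n_genomes pangenome dimensions.
#' @param mixture_spec list of components, each a list with \code{label},
#'   \code{weight}, and either \code{type = "uniform"} with \code{p} or
#'   \code{type = "block"} with \code{p_in}, \code{p_out},
#'   \code{block_frac}; weights must sum to 1 (tolerance 1e-9).
#' @param contiguity_prob probability that two same-component families are
#'   linked in the contiguity graph (cross-component pairs use a tenth of
#'   it).
#' @param cluster_density,background_density within-/cross-pathway edge
#'   probabilities for the PPI generator, in [0, 1].
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 20L,
                             pathway_quotas = c(8L, 1L, 1L, 3L, 5L, 2L),
                             n_docs = 50L,
                             mention_rate = 4,
                             decoy_rate = 0.1,
                             n_families = 300L,
                             n_genomes = 63L,
                             mixture_spec = list(
                               list(label = "persistent", weight = 0.70,
                                    type = "uniform", p = 0.98),
                               list(label = "shell", weight = 0.21,
                                    type = "block", p_in = 0.9, p_out = 0.05,
                                    block_frac = 0.5),
                               list(label = "cloud", weight = 0.09,
                                    type = "uniform", p = 0.03)),
                             contiguity_prob = 0.05,
                             cluster_density = 0.35,
                             background_density = 0.02) {
  if (missing(pathway_quotas) && as.integer(n_genes) != 20L)
    pathway_quotas <- NULL
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              pathway_quotas = pathway_quotas, n_docs = as.integer(n_docs),
              mention_rate = mention_rate, decoy_rate = decoy_rate,
              n_families = as.integer(n_families),
              n_genomes = as.integer(n_genomes),
              mixture_spec = mixture_spec,
              contiguity_prob = contiguity_prob,
              cluster_density = cluster_density,
              background_density = background_density)
  stopIfNot(cfg$n_genes >= 1, "n_genes must be positive")
  stopIfNot(cfg$n_docs >= 0, "n_docs must be non-negative")
  stopIfNot(cfg$n_families >= 1 && cfg$n_genomes >= 1,
            "pangenome dimensions must be positive")
  stopIfNot(cfg$mention_rate >= 0, "mention_rate must be non-negative")
  for (p in c("decoy_rate", "contiguity_prob", "cluster_density",
              "background_density"))
    stopIfNot(cfg[[p]] >= 0 && cfg[[p]] <= 1,
              paste(p, "must lie in [0, 1]"))
  if (!is.null(cfg$pathway_quotas)) {
    stopIfNot(length(cfg$pathway_quotas) == length(pathwayLevels()),
              "pathway_quotas must cover the six pathways")
    stopIfNot(sum(cfg$pathway_quotas) == cfg$n_genes,
              "pathway_quotas must sum to n_genes")
  }
  w <- vapply(cfg$mixture_spec, function(m) m$weight, numeric(1))
  stopIfNot(abs(sum(w) - 1) <= 1e-9, "mixture weights must sum to 1")
  for (m in cfg$mixture_spec) {
    ps <- if (identical(m$type, "block")) c(m$p_in, m$p_out, m$block_frac)
          else m$p
    stopIfNot(all(ps >= 0 & ps <= 1),
              "mixture probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "SimulationConfig")
}

## mean presence probability of a mixture component
componentMeanP <- function(m) {
  if (identical(m$type, "block")) m$block_frac * m$p_in +
    (1 - m$block_frac) * m$p_out
  else m$p
}

fillerVocab <- function() {
  c("anaerobic", "growth", "electron", "acceptor", "reduction", "pathway",
    "mutant", "strain", "culture", "medium", "expression", "protein",
    "activity", "essential", "survival", "metabolism", "analysis",
    "observed", "deletion", "knockout", "sulfate", "lactate", "formate",
    "hydrogen", "genome", "bacterium", "operon", "complex", "subunit",
    "membrane", "periplasmic", "cytoplasmic", "transcription", "regulation")
}

#' Simulate a gene dictionary
#'
#' Generates \code{n_genes} records with \code{dde_}+4-digit locus tags,
#' a unique primary symbol (three-letter stem plus subunit letter), 0-3
#' synonyms, one of the six pathways (honouring \code{pathway_quotas}), a
#' product name, and 1-3 GO terms with aspects.  Byte-identical for a fixed
#' seed.
#'
#' @param config a [simulationConfig()].
#' @return A [GeneDictionary-class].
#' @export
simulateGeneDictionary <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_genes
  set.seed(deriveSeed(config$seed, "dictionary"))
  tags <- sprintf("dde_%04d", sample(1:3999, n))
  stems <- character(0)
  while (length(stems) < n) {
    cand <- apply(matrix(sample(letters, 3 * 2 * n, replace = TRUE),
                         ncol = 3), 1, paste, collapse = "")
    stems <- unique(c(stems, setdiff(cand, fillerVocab())))
  }
  stems <- stems[seq_len(n)]
  symbols <- paste0(stems, sample(LETTERS, n, replace = TRUE))
  n_syn <- sample(0:3, n, replace = TRUE)
  synonyms <- vapply(seq_len(n), function(i) {
    if (n_syn[i] == 0L) return("")
    paste0(stems[i], "_", seq_len(n_syn[i]), sample(letters, n_syn[i]),
           collapse = "|")
  }, character(1))
  quotas <- config$pathway_quotas
  if (is.null(quotas)) {
    quotas <- rep(n %/% 6L, 6L)
    quotas[seq_len(n %% 6L)] <- quotas[seq_len(n %% 6L)] + 1L
  }
  pathway <- rep(pathwayLevels(), times = quotas)
  nouns <- c("reductase", "dehydrogenase", "transporter", "kinase",
             "synthase", "permease", "hydrogenase", "transferase")
  quals <- c("alpha subunit", "beta subunit", "binding protein",
             "membrane component", "catalytic chain", "accessory protein")
  product <- paste(sample(c("Putative", "Probable", "Conserved"), n, TRUE),
                   sample(nouns, n, TRUE), sample(quals, n, TRUE))
  go_pool <- sprintf("GO:%07d", sample(1e4:5e6, 60))
  aspects <- sample(c("F", "P", "C"), 60, replace = TRUE)
  go_terms <- vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    idx <- sample(60, k)
    paste0(go_pool[idx], ":", aspects[idx], collapse = ";")
  }, character(1))
  buildGeneDictionary(data.frame(
    locus_tag = tags, symbol = symbols, synonyms = synonyms,
    product = product, pathway = pathway, go_terms = go_terms,
    stringsAsFactors = FALSE))
}

#' Simulate a literature corpus with planted gene mentions
#'
#' Each document is a token stream of filler vocabulary in which a
#' Poisson(\code{mention_rate}) number of dictionary surface forms (symbols,
#' synonyms or locus tags) are planted at recorded 0-based half-open offsets,
#' and a \code{decoy_rate} fraction of filler tokens is replaced by gene-like
#' decoys (symbol-shaped strings and out-of-range locus tags) that are absent
#' from the dictionary — these fool pattern-based recognizers but not the
#' dictionary matcher.  Gold spans never overlap and always slice back to the
#' mention text.
#'
#' @param dictionary a non-empty [GeneDictionary-class].
#' @param config a [simulationConfig()].
#' @return A list with \code{corpus} (gold [AnnotatedCorpus-class]) and
#'   \code{truth} (list with per-document planted locus tags and the decoy
#'   token set).
#' @export
simulateCorpus <- function(dictionary, config) {
  stopifnot(is(dictionary, "GeneDictionary"),
            inherits(config, "SimulationConfig"))
  stopIfNot(length(dictionary) >= 1, "dictionary must be non-empty")
  set.seed(deriveSeed(config$seed, "corpus"))
  rec <- geneRecords(dictionary)
  lookup <- surfaceLookup(dictionary)
  surfaces <- split(names(lookup), unname(lookup))

  make_decoy <- function(k) {
    repeat {
      d <- c(paste0(apply(matrix(sample(letters, 3 * k, TRUE), ncol = 3), 1,
                          paste, collapse = ""),
                    sample(LETTERS, k, TRUE)),
             sprintf("dde_%04d", sample(4000:8999, k, TRUE)))
      d <- sample(d, k)
      if (!any(normSurface(d) %in% names(lookup))) return(d)
    }
  }

  docs <- vector("list", config$n_docs)
  mens <- vector("list", config$n_docs)
  planted <- vector("list", config$n_docs)
  decoys_used <- character()
  for (i in seq_len(config$n_docs)) {
    n_fill <- sample(30:60, 1)
    tokens <- sample(fillerVocab(), n_fill, replace = TRUE)
    n_dec <- rbinom(1, n_fill, config$decoy_rate)
    if (n_dec > 0) {
      dec <- make_decoy(n_dec)
      tokens[sample(n_fill, n_dec)] <- dec
      decoys_used <- c(decoys_used, dec)
    }
    n_men <- rpois(1, config$mention_rate)
    gene_idx <- if (n_men > 0) sample(nrow(rec), n_men, replace = TRUE)
                else integer()
    men_tok <- vapply(gene_idx, function(g) {
      s <- surfaces[[rec$locus_tag[g]]]
      sample(s, 1)
    }, character(1))
    # interleave mention tokens at sampled gap positions (back to front so
    # earlier gap indices stay valid)
    pos <- sort(sample(length(tokens) + 1L, n_men, replace = TRUE))
    all_tok <- tokens
    is_mention <- logical(length(tokens))
    tag_of <- character(length(tokens))
    for (j in rev(seq_along(men_tok))) {
      all_tok <- append(all_tok, men_tok[j], after = pos[j] - 1L)
      is_mention <- append(is_mention, TRUE, after = pos[j] - 1L)
      tag_of <- append(tag_of, rec$locus_tag[gene_idx[j]],
                       after = pos[j] - 1L)
    }
    text <- paste(all_tok, collapse = " ")
    startpos <- cumsum(c(0L, nchar(all_tok) + 1L))[seq_along(all_tok)]
    mi <- which(is_mention)
    doc_id <- sprintf("doc_%03d", i)
    docs[[i]] <- data.frame(doc_id = doc_id, text = text,
                            stringsAsFactors = FALSE)
    mens[[i]] <- if (length(mi)) {
      data.frame(doc_id = doc_id, start = startpos[mi],
                 end = startpos[mi] + nchar(all_tok[mi]),
                 text = all_tok[mi], locus_tag = tag_of[mi],
                 stringsAsFactors = FALSE)
    } else emptyMentions()
    planted[[doc_id]] <- unique(tag_of[mi])
  }
  men <- do.call(rbind, c(list(emptyMentions()), mens))
  men <- men[order(men$doc_id, men$start), , drop = FALSE]
  rownames(men) <- NULL
  corpus <- new("AnnotatedCorpus",
                documents = do.call(rbind, c(list(data.frame(
                  doc_id = character(), text = character())), docs)),
                mentions = men)
  list(corpus = corpus,
       truth = list(planted = planted, decoys = unique(decoys_used)))
}

#' Simulate a pathway-clustered scored PPI network
#'
#' Nodes are the dictionary's locus tags (with pathway attributes); each
#' within-pathway pair receives an edge with probability
#' \code{cluster_density}, each cross-pathway pair with probability
#' \code{background_density}.  Every edge carries a combined score drawn from
#' [0.5, 1) plus text-mining and experimental channel scores in [0, 1).
#'
#' @inheritParams simulateCorpus
#' @return An [InteractionNetwork-class].
#' @export
simulatePpiNetwork <- function(dictionary, config) {
  stopifnot(is(dictionary, "GeneDictionary"),
            inherits(config, "SimulationConfig"))
  stopIfNot(length(dictionary) >= 1, "dictionary must be non-empty")
  set.seed(deriveSeed(config$seed, "ppi"))
  rec <- geneRecords(dictionary)
  n <- nrow(rec)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- rec$pathway[pairs[, 1]] == rec$pathway[pairs[, 2]]
  prob <- ifelse(same, config$cluster_density, config$background_density)
  keep <- runif(nrow(pairs)) < prob
  a <- rec$locus_tag[pairs[keep, 1]]
  b <- rec$locus_tag[pairs[keep, 2]]
  edges <- data.frame(node_a = a, node_b = b,
                      combined_score = round(runif(sum(keep), 0.5, 0.999), 3),
                      textmining_score = round(runif(sum(keep)), 3),
                      experimental_score = round(runif(sum(keep)), 3),
                      stringsAsFactors = FALSE)
  buildInteractionNetwork(edges, min_score = 0,
                          pathway = setNames(rec$pathway, rec$locus_tag),
                          nodes = rec$locus_tag)
}

#' Simulate a planted-mixture pangenome
#'
#' Draws each family's component from the mixture weights and its
#' presence/absence row as independent Bernoulli draws with the component's
#' per-genome probability: uniform components use a single \code{p}
#' (persistent near 1, cloud near 0), block components use \code{p_in} inside
#' a seed-chosen random genome block of fraction \code{block_frac} and
#' \code{p_out} outside — an environment-dependent shell.  Contiguity edges
#' link same-component family pairs with probability \code{contiguity_prob}
#' and cross-component pairs with a tenth of it.
#'
#' @param config a [simulationConfig()] with >= 2 mixture components of
#'   distinct mean presence probability.
#' @return A list with \code{matrix} ([PresenceAbsenceMatrix-class]),
#'   \code{graph} ([ContiguityGraph-class]) and \code{truth}
#'   (\code{data.frame} of family, component label).
#' @export
simulatePangenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  spec <- config$mixture_spec
  stopIfNot(length(spec) >= 2, "mixture_spec needs >= 2 components")
  means <- vapply(spec, componentMeanP, numeric(1))
  stopIfNot(!anyDuplicated(means),
            "mixture components must have distinct mean presence probabilities")
  set.seed(deriveSeed(config$seed, "pangenome"))
  F_ <- config$n_families; G_ <- config$n_genomes
  labels <- vapply(spec, function(m) m$label, character(1))
  comp <- sample(length(spec), F_, replace = TRUE,
                 prob = vapply(spec, function(m) m$weight, numeric(1)))
  probs <- matrix(NA_real_, length(spec), G_)
  for (k in seq_along(spec)) {
    m <- spec[[k]]
    if (identical(m$type, "block")) {
      blk <- sample(G_, round(m$block_frac * G_))
      probs[k, ] <- m$p_out
      probs[k, blk] <- m$p_in
    } else probs[k, ] <- m$p
  }
  mat <- matrix(rbinom(F_ * G_, 1L, probs[comp, ]), F_, G_)
  rownames(mat) <- sprintf("fam_%04d", seq_len(F_))
  colnames(mat) <- sprintf("genome_%02d", seq_len(G_))
  pa <- presenceAbsenceMatrix(mat)

  pairs <- which(upper.tri(matrix(0, F_, F_)), arr.ind = TRUE)
  same <- comp[pairs[, 1]] == comp[pairs[, 2]]
  p_edge <- ifelse(same, config$contiguity_prob, config$contiguity_prob / 10)
  keep <- runif(nrow(pairs)) < p_edge
  graph <- contiguityGraph(
    data.frame(from = rownames(mat)[pairs[keep, 1]],
               to = rownames(mat)[pairs[keep, 2]],
               weight = rep(1, sum(keep)), stringsAsFactors = FALSE),
    families = rownames(mat))
  truth <- data.frame(family = rownames(mat), component = labels[comp],
                      stringsAsFactors = FALSE)
  list(matrix = pa, graph = graph, truth = truth)
}

#' Write planted truth labels
#'
#' @param truth \code{data.frame} (e.g. from [simulatePangenome()]).
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthLabels <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
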