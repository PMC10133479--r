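# Scored PPI network loading, seed expansion, degree-model enrichment test,
# pathway clustering and bridging-gene detection.

edgeColumns <- c("node_a", "node_b", "combined_score", "textmining_score",
                 "experimental_score")

#' Read a scored interaction edge table
#'
#' The TSV dialect has columns \code{node_a}, \code{node_b},
#' \code{combined_score}, \code{textmining_score}, \code{experimental_score}
#' (scores in [0, 1]).  Duplicate pair rows are merged keeping the row with
#' the maximum combined score; rows with \code{combined_score} below
#' \code{min_score} are dropped.  Malformed rows (missing fields, scores
#' outside [0, 1]) raise a parse error naming the line.
#'
#' @param path edge TSV path.
#' @param min_score combined-score threshold below which rows are dropped
#'   (default 0.4, STRING's medium confidence).
#' @param pathway optional named character vector (locus tag -> pathway)
#'   attached as a node attribute.
#' @return An [InteractionNetwork-class].
#' @export
readInteractionNetwork <- function(path, min_score = 0.4, pathway = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(edgeColumns %in% names(tab)))
    stop("edge table must have columns: ",
         paste(edgeColumns, collapse = ", "), call. = FALSE)
  scores <- c("combined_score", "textmining_score", "experimental_score")
  for (s in scores) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("malformed %s at line %d of %s", s, bad[1] + 1L, path),
           call. = FALSE)
    tab[[s]] <- v
  }
  buildInteractionNetwork(tab, min_score = min_score, pathway = pathway)
}

#' Build an [InteractionNetwork-class] from an edge data.frame
#'
#' @param edges \code{data.frame} in the [readInteractionNetwork()] dialect.
#' @param nodes optional character vector of nodes to include even if
#'   isolated.
#' @inheritParams readInteractionNetwork
#' @return An [InteractionNetwork-class].
#' @export
buildInteractionNetwork <- function(edges, min_score = 0, pathway = NULL,
                                    nodes = NULL) {
  stopIfNot(min_score >= 0 && min_score <= 1, "min_score must be in [0, 1]")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]  # no loops
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b))
    ord <- order(key, -edges$combined_score)
    edges <- edges[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    edges <- edges[edges$combined_score >= min_score, , drop = FALSE]
  }
  verts <- sort(unique(c(edges$node_a, edges$node_b, nodes,
                         names(pathway)[names(pathway) %in% c(edges$node_a, edges$node_b, nodes)])))
  g <- igraph::graph_from_data_frame(
    edges[, intersect(edgeColumns, names(edges)), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  pw <- rep("uncategorized", length(verts))
  if (!is.null(pathway)) {
    hit <- match(verts, names(pathway))
    pw[!is.na(hit)] <- unname(pathway[hit[!is.na(hit)]])
  }
  g <- igraph::set_vertex_attr(g, "pathway", value = pw)
  new("InteractionNetwork", graph = g)
}

#' Expand seed genes to their k-th level interactors
#'
#' Breadth-first expansion: all nodes within graph distance \code{levels} of
#' any seed, using only edges whose combined score is at least
#' \code{min_score}.  Seeds are always part of the result, even when they are
#' isolated or absent from the network (absent seeds raise a warning).
#' The result is monotone in \code{levels} and in decreasing
#' \code{min_score}.
#'
#' @param network an [InteractionNetwork-class].
#' @param seeds character locus tags.
#' @param levels BFS depth (default 2, the "2nd level" expansion).
#' @param min_score combined-score threshold for traversable edges.
#' @param max_per_level optional cap on newly added interactors per level
#'   (highest combined score to a previous-level node first; default
#'   unlimited).
#' @return Sorted character vector of locus tags.
#' @export
expandSeeds <- function(network, seeds, levels = 2L, min_score = 0.4,
                        max_per_level = Inf) {
  stopifnot(is(network, "InteractionNetwork"))
  stopIfNot(levels >= 0, "levels must be >= 0")
  seeds <- unique(as.character(seeds))
  g <- asIgraph(network)
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing))
    warning("seeds absent from network: ", paste(missing, collapse = ", "))
  gs <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$combined_score >= min_score],
    delete.vertices = FALSE)
  frontier <- intersect(seeds, igraph::V(gs)$name)
  visited <- seeds
  lev <- 0L
  while (lev < levels && length(frontier)) {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(gs, frontier),
                               igraph::as_ids)))
    nb <- setdiff(nb, visited)
    if (is.finite(max_per_level) && length(nb) > max_per_level) {
      best <- vapply(nb, function(v) {
        inc <- igraph::incident(gs, v)
        ends <- igraph::ends(gs, inc)
        sel <- ends[, 1] %in% frontier | ends[, 2] %in% frontier
        max(c(inc$combined_score[sel], 0))
      }, numeric(1))
      nb <- nb[order(-best, nb)][seq_len(max_per_level)]
    }
    visited <- c(visited, nb)
    frontier <- nb
    lev <- lev + 1L
  }
  sort(visited)
}

## Observed and degree-model expected internal edge counts for a node set.
edgeStatistics <- function(g, node_set) {
  node_set <- intersect(unique(node_set), igraph::V(g)$name)
  m <- igraph::ecount(g)
  sub <- igraph::induced_subgraph(g, node_set)
  e_obs <- igraph::ecount(sub)
  deg <- igraph::degree(g, v = node_set)
  # expected edges under the degree (Chung-Lu) null, truncated at 1 per pair
  e_exp <- 0
  if (length(deg) >= 2L && m > 0) {
    p <- outer(deg, deg) / (2 * m)
    e_exp <- sum(pmin(p[upper.tri(p)], 1))
  }
  list(e_obs = e_obs, e_exp = e_exp, m = m, nodes = node_set)
}

#' PPI enrichment p-value (degree-model Poisson test)
#'
#' Tests whether a node set contains more internal edges than expected under
#' a degree-preserving null: the expected internal edge count is
#' \eqn{e_{exp} = \sum_{i<j \in S} \min(1, d_i d_j / 2m)} and the p-value is
#' the upper tail \eqn{P(X \ge e_{obs})} for \eqn{X \sim Poisson(e_{exp})}.
#' A singleton (or empty) set has no internal pairs and p-value 1.
#'
#' @param network an [InteractionNetwork-class] (the background graph).
#' @param node_set character locus tags (nodes absent from the background
#'   are ignored for edge counting).
#' @return A list with \code{nodes}, \code{e_obs}, \code{e_exp},
#'   \code{p_value}, \code{method = "analytic"}.
#' @seealso [enrichmentPvaluePermutation()] for the resampling oracle.
#' @export
enrichmentPvalue <- function(network, node_set) {
  stopifnot(is(network, "InteractionNetwork"))
  g <- asIgraph(network)
  if (igraph::ecount(g) == 0)
    stop("background network has no edges; enrichment model undefined",
         call. = FALSE)
  st <- edgeStatistics(g, node_set)
  p <- if (st$e_obs == 0L) 1 else stats::ppois(st$e_obs - 1L, st$e_exp,
                                               lower.tail = FALSE)
  list(nodes = st$nodes, e_obs = st$e_obs, e_exp = st$e_exp,
       p_value = min(1, p), method = "analytic")
}

#' Permutation PPI enrichment p-value
#'
#' Empirical counterpart of [enrichmentPvalue()]: draws \code{n_perm} uniform
#' node sets of the same size and reports the add-one-smoothed upper-tail
#' probability \eqn{(1 + \#\{e_{perm} \ge e_{obs}\}) / (n_{perm} + 1)}.
#'
#' @inheritParams enrichmentPvalue
#' @param n_perm number of random node sets (>= 1).
#' @param seed integer seed.
#' @return A list like [enrichmentPvalue()] with \code{method =
#'   "permutation"}.
#' @export
enrichmentPvaluePermutation <- function(network, node_set, n_perm = 1000L,
                                        seed = 1L) {
  stopifnot(is(network, "InteractionNetwork"))
  stopIfNot(n_perm >= 1, "n_perm must be >= 1")
  g <- asIgraph(network)
  all_nodes <- igraph::V(g)$name
  node_set <- unique(as.character(node_set))
  if (length(node_set) > length(all_nodes))
    stop("node_set larger than the network", call. = FALSE)
  st <- edgeStatistics(g, node_set)
  k <- length(st$nodes)
  set.seed(deriveSeed(seed, "enrichment-perm"))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- sample(all_nodes, k)
    if (igraph::ecount(igraph::induced_subgraph(g, s)) >= st$e_obs)
      hits <- hits + 1L
  }
  list(nodes = st$nodes, e_obs = st$e_obs, e_exp = st$e_exp,
       p_value = (1 + hits) / (n_perm + 1), method = "permutation")
}

#' Cluster an enriched node set by pathway and find bridging genes
#'
#' Partitions the induced subgraph by the nodes' pathway attribute and scores
#' every node by its \emph{bridging degree}: the number of distinct foreign
#' pathway clusters it has at least one edge into.  Bridging genes are the
#' nodes attaining the maximal bridging degree.
#'
#' @param network an [InteractionNetwork-class].
#' @param node_set character locus tags.
#' @param pathway optional named character vector overriding the network's
#'   node pathway attribute.
#' @return A list with \code{clusters} (named list pathway -> node vector),
#'   \code{bridging} (\code{data.frame} of \code{node}, \code{pathway},
#'   \code{bridging_degree}, sorted decreasing), \code{bridging_genes}
#'   (nodes at the maximum) and \code{max_bridging_degree}.
#' @export
clusterByPathway <- function(network, node_set, pathway = NULL) {
  stopifnot(is(network, "InteractionNetwork"))
  g <- asIgraph(network)
  node_set <- intersect(unique(node_set), igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, node_set)
  pw <- igraph::V(sub)$pathway
  if (is.null(pw)) pw <- rep("uncategorized", igraph::vcount(sub))
  if (!is.null(pathway)) {
    hit <- match(igraph::V(sub)$name, names(pathway))
    pw[!is.na(hit)] <- unname(pathway[hit[!is.na(hit)]])
  }
  pw[is.na(pw) | !nzchar(pw)] <- "uncategorized"
  names(pw) <- igraph::V(sub)$name
  clusters <- split(names(pw), pw)

  el <- igraph::as_edgelist(sub)
  bridging <- vapply(names(pw), function(v) {
    nb <- unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
    length(unique(pw[nb][pw[nb] != pw[[v]]]))
  }, integer(1))
  ord <- order(-bridging, names(pw))
  tab <- data.frame(node = names(pw)[ord], pathway = unname(pw[ord]),
                    bridging_degree = unname(bridging[ord]),
                    stringsAsFactors = FALSE)
  mx <- if (length(bridging)) max(bridging) else 0L
  list(clusters = clusters, bridging = tab,
       bridging_genes = tab$node[tab$bridging_degree == mx & mx > 0L],
       max_bridging_degree = mx)
}

#' Write an interaction (sub)network
#'
#' \code{writeInteractionNetwork} writes the edge TSV dialect;
#' \code{writeGraphml} exports the pathway-attributed graph as GraphML for
#' any network viewer.
#'
#' @param network an [InteractionNetwork-class].
#' @param path output file.
#' @param node_set optional subset of nodes (induced subgraph is written).
#' @return \code{path}, invisibly.
#' @export
writeInteractionNetwork <- function(network, path, node_set = NULL) {
  stopifnot(is(network, "InteractionNetwork"))
  g <- asIgraph(network)
  if (!is.null(node_set))
    g <- igraph::induced_subgraph(g, intersect(node_set, igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  tab <- data.frame(node_a = el[, 1], node_b = el[, 2],
                    combined_score = igraph::E(g)$combined_score,
                    textmining_score = igraph::E(g)$textmining_score,
                    experimental_score = igraph::E(g)$experimental_score)
  tab <- tab[order(tab$node_a, tab$node_b), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractionNetwork
#' @export
writeGraphml <- function(network, path, node_set = NULL) {
  stopifnot(is(network, "InteractionNetwork"))
  g <- asIgraph(network)
  if (!is.null(node_set))
    g <- igraph::induced_subgraph(g, intersect(node_set, igraph::V(g)$name))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
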