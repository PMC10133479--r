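# Shared builders and independent oracles used across the test files.
# Oracles are deliberately naive (enumeration, direct formulas) and never
# call the code paths they check.

## small scored network from a 2-column edge matrix
mkNet <- function(el, score = 0.9) {
  buildInteractionNetwork(data.frame(
    node_a = el[, 1], node_b = el[, 2], combined_score = score,
    textmining_score = 0.5, experimental_score = 0.5,
    stringsAsFactors = FALSE))
}

## exhaustive same-size-node-set p-value: fraction of all k-subsets whose
## induced edge count reaches the observed one
enumPvalue <- function(net, node_set) {
  g <- asIgraph(net)
  vs <- igraph::V(g)$name
  k <- length(node_set)
  e_obs <- igraph::ecount(igraph::induced_subgraph(g, node_set))
  sets <- utils::combn(vs, k)
  mean(apply(sets, 2, function(s)
    igraph::ecount(igraph::induced_subgraph(g, s)) >= e_obs))
}

## a hand-built mixture model over G genomes with uniform component profiles
mkModel <- function(levels = c(0.9, 0.5, 0.1), G = 6) {
  K <- length(levels)
  theta <- matrix(rep(levels, G), K, G)
  colnames(theta) <- paste0("g", seq_len(G))
  new("BernoulliMixture", K = as.integer(K), weights = rep(1 / K, K),
      theta = theta, beta = 1, labels = rep(NA_character_, K),
      logLik = 0, iterations = 1L, seed = 1L)
}

## per-family log joint (log pi_k + Bernoulli log-likelihood), direct formula
refLogJoint <- function(X, w, theta) {
  t(vapply(seq_len(nrow(X)), function(f)
    vapply(seq_len(nrow(theta)), function(k)
      log(w[k]) + sum(X[f, ] * log(theta[k, ]) +
                      (1 - X[f, ]) * log(1 - theta[k, ])), numeric(1)),
    numeric(nrow(theta))))
}

## Potts energy of a labelling: unary log joints + beta * agreeing edges
pottsEnergy <- function(labels, lj, graph, beta) {
  fams <- rownames(lj)
  e <- sum(lj[cbind(seq_along(labels), labels)])
  ed <- contiguityEdges(graph)
  if (nrow(ed))
    e <- e + beta * sum(labels[match(ed$from, fams)] ==
                        labels[match(ed$to, fams)])
  e
}

## exhaustive Potts maximization over all K^F labellings (tiny F only)
enumPotts <- function(lj, graph, beta) {
  K <- ncol(lj); F_ <- nrow(lj)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), F_)))
  en <- apply(grid, 1, pottsEnergy, lj = lj, graph = graph, beta = beta)
  list(best = max(en), labels = grid[which.max(en), ])
}

## a deliberately naive pattern recognizer: tags every gene-shaped token
## (three lower-case letters + capital, or a dde_ locus tag) whether or not
## it is in the dictionary -- decoy tokens become false positives
naiveRecognize <- function(corpus, dictionary) {
  doc <- documents(corpus)
  lookup <- surfaceLookup(dictionary)
  men <- lapply(seq_len(nrow(doc)), function(i) {
    text <- doc$text[i]
    m <- gregexpr("(?<![A-Za-z0-9_])([a-z]{3}[A-Z]|dde_[0-9]{4})(?![A-Za-z0-9_])",
                  text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    s <- as.integer(m); e <- s + attr(m, "match.length") - 1L
    txt <- substring(text, s, e)
    tag <- lookup[tolower(txt)]
    tag[is.na(tag)] <- "unknown"
    data.frame(doc_id = doc$doc_id[i], start = s - 1L, end = e, text = txt,
               locus_tag = unname(tag), stringsAsFactors = FALSE)
  })
  men <- do.call(rbind, c(list(essMiner:::emptyMentions()), men))
  new("AnnotatedCorpus", documents = doc, mentions = men)
}

## tiny presence/absence helper
mkPa <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  presenceAbsenceMatrix(m)
}

## the deterministic small-instance family used for the ICM-vs-enumeration
## checks: 3 families on a path, every combination of all-present /
## all-absent / half-present rows, at the operating coupling strengths
icmFamily <- function(betas = c(0, 0.8, 2.5), G = 6) {
  rows <- list(ones = rep(1L, G), zeros = rep(0L, G),
               half = c(rep(1L, ceiling(G / 2)), rep(0L, floor(G / 2))))
  out <- list()
  for (r1 in names(rows)) for (r2 in names(rows)) for (r3 in names(rows))
    for (beta in betas)
      out[[length(out) + 1L]] <- list(
        X = {
          X <- rbind(f1 = rows[[r1]], f2 = rows[[r2]], f3 = rows[[r3]])
          colnames(X) <- paste0("g", seq_len(G)); X
        },
        beta = beta)
  out
}
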