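# Persistent/shell/cloud partitioning of gene families: multivariate
# Bernoulli mixture fitted by EM, Markov-random-field smoothing over the
# family contiguity graph by iterated conditional modes, partition labelling
# and query-gene mapping.

THETA_EPS <- 1e-4  # clamp for theta: avoids log(0) and degenerate components

#' Construct a presence/absence matrix
#'
#' @param mat binary matrix, rows = gene families, columns = genomes, with
#'   dimnames.
#' @return A [PresenceAbsenceMatrix-class].
#' @export
presenceAbsenceMatrix <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  new("PresenceAbsenceMatrix", mat = mat)
}

#' Read / write the presence/absence CSV
#'
#' Rows are gene families, columns genomes; entries are 1 when at least one
#' member of the family is present in the genome, else 0.  Families present
#' in no genome carry no information for the mixture model and are rejected
#' (dropped with a warning) at load.
#'
#' @param path CSV path (first column = family id).
#' @param pa a [PresenceAbsenceMatrix-class].
#' @return \code{readPresenceAbsence} returns a
#'   [PresenceAbsenceMatrix-class]; the writer returns \code{path} invisibly.
#' @export
readPresenceAbsence <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (length(m) && !all(m %in% c(0, 1)))
    stop("presence/absence entries must be 0/1", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " families observed in zero genomes: ",
            paste(utils::head(rownames(m)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ...")
    m <- m[!zero, , drop = FALSE]
  }
  presenceAbsenceMatrix(m)
}

#' @rdname readPresenceAbsence
#' @export
writePresenceAbsence <- function(pa, path) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  utils::write.csv(paMatrix(pa), path, quote = FALSE)
  invisible(path)
}

#' Construct / read / write a family contiguity graph
#'
#' Edge TSV dialect: columns \code{from}, \code{to}, optional \code{weight}
#' (default 1).
#'
#' @param edges \code{data.frame} with \code{from}, \code{to}, optional
#'   \code{weight}.
#' @param families character universe of family ids.
#' @param path file path.
#' @param graph a [ContiguityGraph-class].
#' @return A [ContiguityGraph-class] (readers/constructor); \code{path}
#'   invisibly (writer).
#' @export
contiguityGraph <- function(edges, families) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  new("ContiguityGraph", edges = edges[, c("from", "to", "weight")],
      families = as.character(families))
}

#' @rdname contiguityGraph
#' @export
readContiguityGraph <- function(path, families) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  # edges touching families not in the universe (e.g. all-zero families
  # dropped by readPresenceAbsence) are discarded
  keep <- tab$from %in% families & tab$to %in% families
  contiguityGraph(tab[keep, , drop = FALSE], families)
}

#' @rdname contiguityGraph
#' @export
writeContiguityGraph <- function(graph, path) {
  stopifnot(is(graph, "ContiguityGraph"))
  utils::write.table(contiguityEdges(graph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## F x K matrix of log( pi_k * Bernoulli(x_f | theta_k) ), computed in
## log-space: log pi_k + sum_g x log theta + (1-x) log(1-theta).
componentLogJoint <- function(X, weights, theta) {
  lt <- log(theta)
  l1t <- log1p(-theta)
  lj <- X %*% t(lt - l1t)
  sweep(lj, 2L, rowSums(l1t) + log(weights), `+`)
}

#' Log-likelihood of a presence/absence matrix under a mixture model
#'
#' \eqn{\sum_f \log \sum_k \pi_k \prod_g \theta_{k,g}^{x_{fg}}
#' (1-\theta_{k,g})^{1-x_{fg}}}, computed in log-space.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param model a [BernoulliMixture-class] with matching genome dimension.
#' @return Numeric scalar.
#' @export
bmmLogLikelihood <- function(pa, model) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"), is(model, "BernoulliMixture"))
  X <- paMatrix(pa)
  if (ncol(X) != ncol(model@theta))
    stop("genome dimension mismatch between matrix and model", call. = FALSE)
  sum(logRowSumExp(componentLogJoint(X, mixingWeights(model),
                                     presenceProfiles(model))))
}

#' Fit a multivariate Bernoulli mixture by EM
#'
#' The presence/absence matrix is modelled as a K-component mixture of
#' independent per-genome Bernoulli profiles.  The E-step computes
#' responsibilities in log-space; the M-step updates mixing weights and
#' \eqn{\theta_{k,g}} from responsibility-weighted counts,
#' clamping \eqn{\theta} to \eqn{[10^{-4}, 1-10^{-4}]}.  Iteration stops when
#' the relative log-likelihood change drops below \code{tol} or after
#' \code{max_iter} iterations.  Initialization sorts families by row mean
#' presence, splits them into K equal bins, sets each component's profile to
#' its bin's column means, and adds a small seed-controlled jitter.  The
#' log-likelihood is asserted non-decreasing at every iteration (tolerance
#' 1e-9).
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param K component count (1 <= K <= number of families).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param seed integer seed for initialization jitter.
#' @param beta MRF coupling strength stored on the model for downstream
#'   smoothing (default 2.5).
#' @return A list with \code{model} (a [BernoulliMixture-class], labels
#'   unset), \code{responsibilities} (F x K, rows sum to 1), \code{logLik}
#'   and \code{trace} (per-iteration log-likelihood).
#' @examples
#' pa <- simulatePangenome(simulationConfig(seed = 7, n_families = 60,
#'                                          n_genomes = 12))$matrix
#' fit <- fitBernoulliMixture(pa, K = 3, seed = 7)
#' fit$model
#' @export
fitBernoulliMixture <- function(pa, K = 3L, tol = 1e-6, max_iter = 500L,
                                seed = 1L, beta = 2.5) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  X <- paMatrix(pa)
  F_ <- nrow(X)
  stopIfNot(F_ >= 1, "matrix must be non-empty")
  stopIfNot(K >= 1, "K must be >= 1")
  if (K > F_)
    stop("K exceeds the number of families", call. = FALSE)

  ## presence-frequency binning with seeded jitter: the [min, max] frequency
  ## range is split into K equal intervals so minority components (e.g. a
  ## small cloud under a dominant persistent mass) seed their own bin; an
  ## empty bin starts at its interval midpoint
  set.seed(deriveSeed(seed, "bmm-init"))
  freq <- rowMeans(X)
  rng <- range(freq)
  if (diff(rng) < 1e-12) rng <- c(max(0, rng[1] - 0.1), min(1, rng[2] + 0.1))
  breaks <- seq(rng[1], rng[2], length.out = K + 1L)
  bin <- cut(freq, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (breaks[-1] + breaks[-(K + 1L)]) / 2
  theta <- do.call(rbind, lapply(seq_len(K), function(k) {
    idx <- which(bin == k)
    if (length(idx)) colMeans(X[idx, , drop = FALSE])
    else rep(mids[k], ncol(X))
  }))
  # per-component jitter (not per-cell) so that permuting genome columns
  # permutes the fitted theta columns exactly
  theta <- theta + runif(K, -0.01, 0.01)
  theta <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
  weights <- (tabulate(bin, nbins = K) + 1) / (F_ + K)
  colnames(theta) <- colnames(X)

  ll_old <- -Inf
  trace <- numeric()
  resp <- matrix(1 / K, F_, K)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lj <- componentLogJoint(X, weights, theta)
    lse <- logRowSumExp(lj)
    ll <- sum(lse)
    if (ll < ll_old - 1e-9)
      stop(sprintf("EM log-likelihood decreased (%.12g -> %.12g)", ll_old, ll))
    trace <- c(trace, ll)
    resp <- exp(lj - lse)
    if ((is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) ||
        iter >= max_iter) break
    ll_old <- ll
    nk <- colSums(resp)
    weights <- nk / F_
    theta <- (t(resp) %*% X) / nk
    theta <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
  }
  rownames(resp) <- rownames(X)
  model <- new("BernoulliMixture", K = as.integer(K), weights = unname(weights),
               theta = theta, beta = beta,
               labels = rep(NA_character_, K), logLik = trace[length(trace)],
               iterations = iter, seed = as.integer(seed))
  list(model = model, responsibilities = resp, logLik = model@logLik,
       trace = trace)
}

#' Smooth component assignments by iterated conditional modes
#'
#' Hard-label MRF smoothing over the family contiguity graph: starting from
#' the per-family argmax of the responsibilities, families are swept in input
#' order and each is reassigned to the component maximizing
#' \deqn{\log \pi_k + \log P(x_f | \theta_k) + \beta \cdot
#'   \#\{neighbors\ currently\ assigned\ k\},}
#' until no label changes or \code{n_sweeps} sweeps have run.  With
#' \eqn{\beta = 0} (or an edgeless graph) this reduces to the responsibility
#' argmax.  Ties go to the lowest component index.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param fit the list returned by [fitBernoulliMixture()] (or a list with
#'   \code{model} and \code{responsibilities}).
#' @param graph a [ContiguityGraph-class] over the matrix's families (or
#'   \code{NULL} for no coupling).
#' @param beta MRF coupling strength (>= 0); defaults to the model's value.
#' @param n_sweeps maximum ICM sweeps (default 10).
#' @return Integer vector of component assignments (named by family).
#' @export
smoothLabelsICM <- function(pa, fit, graph = NULL, beta = NULL,
                            n_sweeps = 10L) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  model <- fit$model
  stopifnot(is(model, "BernoulliMixture"))
  if (is.null(beta)) beta <- model@beta
  stopIfNot(beta >= 0, "beta must be >= 0")
  X <- paMatrix(pa)
  fams <- rownames(X)
  lj <- componentLogJoint(X, mixingWeights(model), presenceProfiles(model))
  assign <- max.col(lj, ties.method = "first")
  if (is.null(graph) || !nrow(contiguityEdges(graph)) || beta == 0) {
    return(setNames(assign, fams))
  }
  e <- contiguityEdges(graph)
  idx <- seq_len(nrow(X))
  nbrs <- vector("list", nrow(X))
  ef <- match(e$from, fams); et <- match(e$to, fams)
  ok <- !is.na(ef) & !is.na(et)
  for (r in which(ok)) {
    nbrs[[ef[r]]] <- c(nbrs[[ef[r]]], et[r])
    nbrs[[et[r]]] <- c(nbrs[[et[r]]], ef[r])
  }
  K <- model@K
  for (sweep_i in seq_len(n_sweeps)) {
    changed <- FALSE
    for (f in idx) {
      score <- lj[f, ]
      if (length(nbrs[[f]])) {
        cnt <- tabulate(assign[nbrs[[f]]], nbins = K)
        score <- score + beta * cnt
      }
      new_k <- which.max(score)  # lowest index on ties
      if (new_k != assign[f]) {
        assign[f] <- new_k
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  setNames(assign, fams)
}

#' Label components and assign partitions
#'
#' Components are ranked by their mean presence probability
#' \eqn{\bar\theta_k}: the highest becomes \code{persistent}, the lowest
#' \code{cloud}, every middle component \code{shell} (so K > 3 yields several
#' shell components; K = 2, allowed with \code{allow_k2 = TRUE}, has no
#' shell).  \eqn{\bar\theta_k} ties within 1e-9 are broken by component index
#' and reported via a message.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param fit the list returned by [fitBernoulliMixture()].
#' @param component integer component per family, typically from
#'   [smoothLabelsICM()]; defaults to the responsibility argmax.
#' @param allow_k2 allow a 2-component model with no shell partition.
#' @return A [PartitionResult-class].
#' @export
assignPartitions <- function(pa, fit, component = NULL, allow_k2 = FALSE) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  model <- fit$model
  resp <- fit$responsibilities
  K <- model@K
  if (K < 3L && !(K == 2L && allow_k2))
    stop("labelling persistent/shell/cloud needs K >= 3 (or K = 2 with ",
         "allow_k2 = TRUE)", call. = FALSE)
  X <- paMatrix(pa)
  if (is.null(component)) component <- max.col(componentLogJoint(
    X, mixingWeights(model), presenceProfiles(model)), ties.method = "first")
  tbar <- rowMeans(presenceProfiles(model))
  if (anyDuplicated(round(tbar / 1e-9)))
    message("mean presence probabilities tied within 1e-9; ",
            "breaking ties by component index")
  rk <- rank(tbar, ties.method = "first")
  labels <- rep("shell", K)
  labels[which.max(rk)] <- "persistent"
  labels[which.min(rk)] <- "cloud"
  model@labels <- labels
  res <- new("PartitionResult", families = rownames(X),
             partition = labels[component],
             component = as.integer(unname(component)),
             responsibilities = resp,
             frequency = unname(rowMeans(X)), model = model)
  validObject(res)
  res
}

#' Map query genes onto partitioned families
#'
#' Joins a query table (gene -> family, with alignment quality columns
#' \code{pident}, \code{evalue}, \code{bit_score} passed through) onto a
#' [PartitionResult-class].  Queries naming no known family are reported
#' separately, not dropped silently.
#'
#' @param queries \code{data.frame} with columns \code{gene}, \code{family}
#'   and optionally \code{pident}, \code{evalue}, \code{bit_score}.
#' @param result a [PartitionResult-class].
#' @return A list with \code{table} (one row per matched query: gene,
#'   family, partition, quality columns) and \code{unmatched}
#'   (\code{data.frame} of queries naming unknown families).
#' @export
mapQueryGenes <- function(queries, result) {
  stopifnot(is(result, "PartitionResult"))
  queries <- as.data.frame(queries, stringsAsFactors = FALSE)
  qual <- intersect(c("pident", "evalue", "bit_score"), names(queries))
  if (!nrow(queries)) {
    empty <- data.frame(gene = character(), family = character(),
                        partition = character(), stringsAsFactors = FALSE)
    return(list(table = empty, unmatched = empty))
  }
  part <- partitions(result)
  hit <- match(queries$family, names(part))
  ok <- !is.na(hit)
  tab <- cbind(data.frame(gene = queries$gene[ok], family = queries$family[ok],
                          partition = unname(part[hit[ok]]),
                          stringsAsFactors = FALSE),
               queries[ok, qual, drop = FALSE])
  rownames(tab) <- NULL
  list(table = tab, unmatched = queries[!ok, , drop = FALSE])
}

#' Write partition results and the fitted model
#'
#' The partition TSV has one row per family with the assigned partition and
#' the responsibility mass aggregated per partition label; the model JSON
#' records \eqn{\pi}, \eqn{\theta}, \eqn{\beta}, K and the seed.
#'
#' @param result a [PartitionResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePartitionResult <- function(result, path) {
  stopifnot(is(result, "PartitionResult"))
  labels <- componentLabels(result@model)
  resp <- responsibilities(result)
  agg <- vapply(partitionLevels(), function(lb) {
    cols <- which(labels == lb)
    if (!length(cols)) return(rep(0, nrow(resp)))
    rowSums(resp[, cols, drop = FALSE])
  }, numeric(nrow(resp)))
  tab <- data.frame(family = familyIds(result),
                    partition = result@partition,
                    responsibility_persistent = agg[, "persistent"],
                    responsibility_shell = agg[, "shell"],
                    responsibility_cloud = agg[, "cloud"],
                    frequency = result@frequency)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartitionResult
#' @param model a [BernoulliMixture-class].
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "BernoulliMixture"))
  obj <- list(K = model@K, weights = model@weights,
              theta = apply(model@theta, 1L, identity, simplify = FALSE),
              genomes = colnames(model@theta), beta = model@beta,
              labels = model@labels, logLik = model@logLik,
              iterations = model@iterations, seed = model@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
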