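#' @import methods
NULL

#' Gene dictionary for an organism
#'
#' Keyed by locus tag, a \code{GeneDictionary} holds one record per gene
#' (primary symbol, synonyms, product name, pathway label, GO terms with
#' aspects) together with a normalized surface-form lookup used by the
#' annotator and the genome mapper.  Surface forms are the case-folded
#' primary symbol, every synonym, and the locus tag itself; a surface form
#' mapping to two locus tags is an ambiguity and is rejected at build time.
#'
#' @slot records a \code{data.frame} with columns \code{locus_tag},
#'   \code{symbol}, \code{synonyms} (\code{|}-separated, possibly empty),
#'   \code{product}, \code{pathway}, \code{go_terms}
#'   (\code{;}-separated \code{GO:NNNNNNN:A} entries where \code{A} is one of
#'   \code{F}, \code{P}, \code{C}).
#' @slot lookup named character vector mapping normalized surface forms to
#'   locus tags.
#'
#' @seealso [buildGeneDictionary()], [readGeneDictionary()],
#'   [annotateDocument()]
#' @export
setClass("GeneDictionary",
  representation(records = "data.frame", lookup = "character"))

setValidity("GeneDictionary", function(object) {
  rec <- object@records
  need <- c("locus_tag", "symbol", "synonyms", "product", "pathway",
            "go_terms")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$locus_tag))
    return("duplicate locus tags")
  lk <- object@lookup
  if (length(lk) && (is.null(names(lk)) || anyDuplicated(names(lk))))
    return("lookup surface forms must be uniquely named")
  if (length(lk) && !all(lk %in% rec$locus_tag))
    return("lookup values must be known locus tags")
  TRUE
})

#' Annotated document corpus
#'
#' A set of free-text documents with character-offset gene mentions (gold or
#' predicted).  Offsets are 0-based half-open, so
#' \code{substr(text, start + 1, end)} recovers the surface text.  Mentions
#' within a document are sorted by start and never overlap.
#'
#' @slot documents \code{data.frame} with columns \code{doc_id}, \code{text}.
#' @slot mentions \code{data.frame} with columns \code{doc_id}, \code{start},
#'   \code{end}, \code{text}, \code{locus_tag}.
#'
#' @seealso [annotateCorpus()], [readCorpusJsonl()], [evaluateMentions()]
#' @export
setClass("AnnotatedCorpus",
  representation(documents = "data.frame", mentions = "data.frame"))

setValidity("AnnotatedCorpus", function(object) {
  doc <- object@documents
  men <- object@mentions
  if (!all(c("doc_id", "text") %in% names(doc)))
    return("documents needs doc_id, text")
  if (anyDuplicated(doc$doc_id)) return("duplicate doc_id")
  need <- c("doc_id", "start", "end", "text", "locus_tag")
  if (!all(need %in% names(men)))
    return(paste("mentions needs", paste(need, collapse = ", ")))
  if (nrow(men)) {
    if (!all(men$doc_id %in% doc$doc_id))
      return("mention doc_id absent from documents")
    if (any(men$start < 0) || any(men$end <= men$start))
      return("mention offsets must satisfy 0 <= start < end")
    n <- nchar(doc$text)[match(men$doc_id, doc$doc_id)]
    if (any(men$end > n))
      return("mention end beyond document length")
    sl <- substr(doc$text[match(men$doc_id, doc$doc_id)],
                 men$start + 1L, men$end)
    if (!all(sl == men$text))
      return("mention text does not match its offsets")
    by_doc <- split(men[order(men$doc_id, men$start), ], men$doc_id[order(men$doc_id, men$start)])
    for (d in by_doc) {
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
        return("overlapping mentions within a document")
    }
  }
  TRUE
})

#' Scored protein-protein interaction network
#'
#' An undirected simple graph over locus tags.  Each edge carries a STRING-like
#' \code{combined_score} plus \code{textmining_score} and
#' \code{experimental_score}, all in [0, 1].  Nodes may carry a
#' \code{pathway} attribute used by the pathway clustering step.
#'
#' @slot graph an \code{igraph} object.
#'
#' @seealso [readInteractionNetwork()], [expandSeeds()], [enrichmentPvalue()]
#' @export
setClass("InteractionNetwork", representation(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multiedges)")
  for (s in c("combined_score", "textmining_score", "experimental_score")) {
    v <- igraph::edge_attr(g, s)
    if (igraph::ecount(g) && (is.null(v) || any(v < 0 | v > 1, na.rm = TRUE)))
      return(paste(s, "must be present and within [0, 1]"))
  }
  TRUE
})

#' Gene-family presence/absence matrix
#'
#' Binary matrix with gene families as rows and genomes as columns; an entry
#' is 1 when at least one member of the family occurs in the genome and 0
#' otherwise.  The container allows all-zero rows (degenerate generator
#' settings produce them); [readPresenceAbsence()] drops them at load since
#' they carry no information for the mixture model.
#'
#' @slot mat binary integer matrix with unique row (family) and column
#'   (genome) names.
#'
#' @seealso [fitBernoulliMixture()], [simulatePangenome()]
#' @export
setClass("PresenceAbsenceMatrix", representation(mat = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix needs family rownames and genome colnames")
  if (anyDuplicated(rownames(m))) return("duplicate family ids")
  if (anyDuplicated(colnames(m))) return("duplicate genome ids")
  if (length(m) && !all(m %in% c(0L, 1L))) return("entries must be 0/1")
  TRUE
})

#' Gene-family contiguity graph
#'
#' Undirected simple graph over family identifiers in which an edge records
#' genetic contiguity: two families are linked when they contain genes that
#' are neighbors on some genome.  Used as the Markov-random-field coupling
#' structure when smoothing partition labels.
#'
#' @slot edges \code{data.frame} with columns \code{from}, \code{to},
#'   \code{weight}.
#' @slot families character vector of all family identifiers.
#'
#' @seealso [smoothLabelsICM()], [simulatePangenome()]
#' @export
setClass("ContiguityGraph",
  representation(edges = "data.frame", families = "character"))

setValidity("ContiguityGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges needs from, to, weight")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@families))
      return("edge endpoint not among families")
    if (any(e$from == e$to)) return("self-loops not allowed")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) return("parallel edges not allowed")
  }
  if (anyDuplicated(object@families)) return("duplicate family ids")
  TRUE
})

#' Multivariate Bernoulli mixture model
#'
#' The fitted pangenome partition model: \code{K} components with mixing
#' weights \eqn{\pi_k} and per-component, per-genome presence probabilities
#' \eqn{\theta_{k,g}} (clamped to \eqn{[\epsilon, 1-\epsilon]}), plus the
#' MRF coupling strength \eqn{\beta} and the partition label attached to each
#' component after ranking by mean presence probability.
#'
#' @slot K integer component count.
#' @slot weights numeric mixing weights, sum to 1.
#' @slot theta K x G numeric matrix of presence probabilities (columns named
#'   by genome).
#' @slot beta numeric MRF coupling strength.
#' @slot labels character of length K: \code{persistent}, \code{shell}
#'   (possibly \code{shell} repeated for several middle components) or
#'   \code{cloud}; \code{NA} before ranking.
#' @slot logLik numeric final log-likelihood.
#' @slot iterations integer EM iterations run.
#' @slot seed integer seed used for initialization jitter.
#'
#' @seealso [fitBernoulliMixture()], [assignPartitions()]
#' @export
setClass("BernoulliMixture",
  representation(K = "integer", weights = "numeric", theta = "matrix",
                 beta = "numeric", labels = "character", logLik = "numeric",
                 iterations = "integer", seed = "integer"))

setValidity("BernoulliMixture", function(object) {
  if (length(object@weights) != object@K) return("length(weights) != K")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (nrow(object@theta) != object@K) return("nrow(theta) != K")
  if (any(object@theta <= 0 | object@theta >= 1))
    return("theta must lie strictly inside (0, 1)")
  if (length(object@labels) != object@K) return("length(labels) != K")
  TRUE
})

#' Pangenome partition result
#'
#' Per-family partition assignment together with the posterior responsibility
#' vector and the mean presence frequency, plus the fitted model.
#'
#' @slot families character family identifiers.
#' @slot partition character partition per family
#'   (\code{persistent}/\code{shell}/\code{cloud}).
#' @slot component integer index of the assigned mixture component.
#' @slot responsibilities F x K numeric matrix, rows sum to 1.
#' @slot frequency numeric mean presence across genomes per family.
#' @slot model the fitted [BernoulliMixture-class].
#'
#' @seealso [assignPartitions()], [mapQueryGenes()], [segregatePartitions()]
#' @export
setClass("PartitionResult",
  representation(families = "character", partition = "character",
                 component = "integer", responsibilities = "matrix",
                 frequency = "numeric", model = "BernoulliMixture"))

setValidity("PartitionResult", function(object) {
  n <- length(object@families)
  if (length(object@partition) != n || length(object@frequency) != n ||
      length(object@component) != n || nrow(object@responsibilities) != n)
    return("per-family slots must have one entry per family")
  if (n && any(abs(rowSums(object@responsibilities) - 1) > 1e-6))
    return("responsibilities must row-sum to 1")
  if (!all(object@partition %in% partitionLevels()))
    return("partition labels must be persistent/shell/cloud")
  TRUE
})

#' Symbol-to-genome mapping funnel
#'
#' Records the full mined-symbol funnel: the input symbol list, the entries
#' that mapped to the genome, those that did not (the stand-in for symbols
#' with no homolog in the target genus), and after deduplication the removed
#' entries (with reason \code{duplicate-locus} or \code{duplicate-product})
#' and the retained set.
#'
#' @slot input character input symbols as given.
#' @slot mapped \code{data.frame} with \code{symbol}, \code{locus_tag},
#'   \code{product}, \code{pathway}.
#' @slot unmapped character symbols with no dictionary hit.
#' @slot removed \code{data.frame} like \code{mapped} plus \code{reason}.
#' @slot retained \code{data.frame} like \code{mapped}.
#'
#' @seealso [mapToGenome()], [deduplicateMapped()]
#' @export
setClass("MappingFunnel",
  representation(input = "character", mapped = "data.frame",
                 unmapped = "character", removed = "data.frame",
                 retained = "data.frame"))

setValidity("MappingFunnel", function(object) {
  if (nrow(object@mapped) + length(object@unmapped) != length(object@input))
    return("|input| must equal |mapped| + |unmapped|")
  if (nrow(object@retained) &&
      nrow(object@removed) + nrow(object@retained) != nrow(object@mapped))
    return("|mapped| must equal |removed| + |retained|")
  if (anyDuplicated(object@retained$locus_tag))
    return("retained locus tags must be unique")
  TRUE
})

#' Mention-level evaluation result
#'
#' Exact-span precision/recall/F1 of predicted against gold mentions, with
#' optional per-slice scores and their mean ("average") and best F1.
#' 0/0 precision and recall are defined as 0.
#'
#' @slot tp,fp,fn integer counts.
#' @slot precision,recall,f1 numeric in [0, 1].
#' @slot slices \code{data.frame} with per-slice \code{slice}, \code{tp},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall}, \code{f1}
#'   (zero rows when unsliced).
#' @slot mean_f1,best_f1 numeric; equal to \code{f1} when unsliced.
#'
#' @seealso [evaluateMentions()], [sliceEvaluate()]
#' @export
setClass("EvalResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 slices = "data.frame", mean_f1 = "numeric",
                 best_f1 = "numeric"))

setValidity("EvalResult", function(object) {
  if (object@best_f1 < object@mean_f1 - 1e-12)
    return("best_f1 must be >= mean_f1")
  for (s in c("precision", "recall", "f1"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      return(paste(s, "must lie in [0, 1]"))
  TRUE
})
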