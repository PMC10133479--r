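# Generics and accessors.  Slot access from user code goes through these.

#' @name essMiner-accessors
#' @title Accessors for essMiner classes
#' @description Accessor generics for the workflow's S4 containers.
#' @param x an essMiner object.
#' @param object an essMiner object (for \code{show}).
#' @return The corresponding slot content; see the class documentation.
#' @examples
#' d <- loadFixtures()$dictionary
#' length(locusTags(d))
NULL

#' @rdname essMiner-accessors
#' @export
setGeneric("geneRecords", function(x) standardGeneric("geneRecords"))
#' @rdname essMiner-accessors
#' @export
setGeneric("locusTags", function(x) standardGeneric("locusTags"))
#' @rdname essMiner-accessors
#' @export
setGeneric("surfaceLookup", function(x) standardGeneric("surfaceLookup"))
#' @rdname essMiner-accessors
#' @export
setGeneric("documents", function(x) standardGeneric("documents"))
#' @rdname essMiner-accessors
#' @export
setGeneric("mentions", function(x) standardGeneric("mentions"))
#' @rdname essMiner-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname essMiner-accessors
#' @export
setGeneric("paMatrix", function(x) standardGeneric("paMatrix"))
#' @rdname essMiner-accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))
#' @rdname essMiner-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname essMiner-accessors
#' @export
setGeneric("contiguityEdges", function(x) standardGeneric("contiguityEdges"))
#' @rdname essMiner-accessors
#' @export
setGeneric("mixingWeights", function(x) standardGeneric("mixingWeights"))
#' @rdname essMiner-accessors
#' @export
setGeneric("presenceProfiles", function(x) standardGeneric("presenceProfiles"))
#' @rdname essMiner-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname essMiner-accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))
#' @rdname essMiner-accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))
#' @rdname essMiner-accessors
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))
#' @rdname essMiner-accessors
#' @export
setGeneric("mappedGenes", function(x) standardGeneric("mappedGenes"))
#' @rdname essMiner-accessors
#' @export
setGeneric("unmappedSymbols", function(x) standardGeneric("unmappedSymbols"))
#' @rdname essMiner-accessors
#' @export
setGeneric("removedGenes", function(x) standardGeneric("removedGenes"))
#' @rdname essMiner-accessors
#' @export
setGeneric("retainedGenes", function(x) standardGeneric("retainedGenes"))
#' @rdname essMiner-accessors
#' @export
setGeneric("evalScores", function(x) standardGeneric("evalScores"))
#' @rdname essMiner-accessors
#' @export
setGeneric("sliceScores", function(x) standardGeneric("sliceScores"))

#' @rdname essMiner-accessors
setMethod("geneRecords", "GeneDictionary", function(x) x@records)
#' @rdname essMiner-accessors
setMethod("locusTags", "GeneDictionary", function(x) x@records$locus_tag)
#' @rdname essMiner-accessors
setMethod("surfaceLookup", "GeneDictionary", function(x) x@lookup)
#' @rdname essMiner-accessors
setMethod("documents", "AnnotatedCorpus", function(x) x@documents)
#' @rdname essMiner-accessors
setMethod("mentions", "AnnotatedCorpus", function(x) x@mentions)
#' @rdname essMiner-accessors
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)
#' @rdname essMiner-accessors
setMethod("paMatrix", "PresenceAbsenceMatrix", function(x) x@mat)
#' @rdname essMiner-accessors
setMethod("familyIds", "PresenceAbsenceMatrix", function(x) rownames(x@mat))
#' @rdname essMiner-accessors
setMethod("genomeIds", "PresenceAbsenceMatrix", function(x) colnames(x@mat))
#' @rdname essMiner-accessors
setMethod("familyIds", "ContiguityGraph", function(x) x@families)
#' @rdname essMiner-accessors
setMethod("contiguityEdges", "ContiguityGraph", function(x) x@edges)
#' @rdname essMiner-accessors
setMethod("mixingWeights", "BernoulliMixture", function(x) x@weights)
#' @rdname essMiner-accessors
setMethod("presenceProfiles", "BernoulliMixture", function(x) x@theta)
#' @rdname essMiner-accessors
setMethod("nComponents", "BernoulliMixture", function(x) x@K)
#' @rdname essMiner-accessors
setMethod("componentLabels", "BernoulliMixture", function(x) x@labels)
#' @rdname essMiner-accessors
setMethod("familyIds", "PartitionResult", function(x) x@families)
#' @rdname essMiner-accessors
setMethod("partitions", "PartitionResult",
          function(x) setNames(x@partition, x@families))
#' @rdname essMiner-accessors
setMethod("responsibilities", "PartitionResult",
          function(x) x@responsibilities)
#' @rdname essMiner-accessors
setMethod("mappedGenes", "MappingFunnel", function(x) x@mapped)
#' @rdname essMiner-accessors
setMethod("unmappedSymbols", "MappingFunnel", function(x) x@unmapped)
#' @rdname essMiner-accessors
setMethod("removedGenes", "MappingFunnel", function(x) x@removed)
#' @rdname essMiner-accessors
setMethod("retainedGenes", "MappingFunnel", function(x) x@retained)
#' @rdname essMiner-accessors
setMethod("evalScores", "EvalResult", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, precision = x@precision,
    recall = x@recall, f1 = x@f1, mean_f1 = x@mean_f1, best_f1 = x@best_f1))
#' @rdname essMiner-accessors
setMethod("sliceScores", "EvalResult", function(x) x@slices)

#' @rdname essMiner-accessors
setMethod("length", "GeneDictionary", function(x) nrow(x@records))

#' @rdname essMiner-accessors
setMethod("show", "GeneDictionary", function(object) {
  cat("GeneDictionary with", nrow(object@records), "genes and",
      length(object@lookup), "surface forms\n")
  pw <- table(object@records$pathway)
  cat("  pathways:", paste(names(pw), pw, sep = "=", collapse = ", "), "\n")
})

#' @rdname essMiner-accessors
setMethod("show", "AnnotatedCorpus", function(object) {
  cat("AnnotatedCorpus:", nrow(object@documents), "documents,",
      nrow(object@mentions), "mentions (",
      length(unique(object@mentions$locus_tag)), "distinct genes )\n")
})

#' @rdname essMiner-accessors
setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat("InteractionNetwork:", igraph::vcount(g), "proteins,",
      igraph::ecount(g), "interactions\n")
})

#' @rdname essMiner-accessors
setMethod("show", "PresenceAbsenceMatrix", function(object) {
  m <- object@mat
  cat("PresenceAbsenceMatrix:", nrow(m), "gene families x", ncol(m),
      "genomes; fill", sprintf("%.3f", mean(m)), "\n")
})

#' @rdname essMiner-accessors
setMethod("show", "ContiguityGraph", function(object) {
  cat("ContiguityGraph:", length(object@families), "families,",
      nrow(object@edges), "contiguity edges\n")
})

#' @rdname essMiner-accessors
setMethod("show", "BernoulliMixture", function(object) {
  cat("BernoulliMixture: K =", object@K, ", logLik =",
      sprintf("%.4f", object@logLik), "(", object@iterations, "EM iterations )\n")
  tb <- rowMeans(object@theta)
  for (k in seq_len(object@K))
    cat(sprintf("  component %d [%s]: pi = %.3f, mean theta = %.3f\n",
                k, ifelse(is.na(object@labels[k]), "?", object@labels[k]),
                object@weights[k], tb[k]))
})

#' @rdname essMiner-accessors
setMethod("show", "PartitionResult", function(object) {
  tb <- table(factor(object@partition, levels = partitionLevels()))
  cat("PartitionResult over", length(object@families), "families:",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

#' @rdname essMiner-accessors
setMethod("show", "MappingFunnel", function(object) {
  cat("MappingFunnel:", length(object@input), "symbols ->",
      nrow(object@mapped), "mapped (", length(object@unmapped),
      "unmapped ) ->", nrow(object@retained), "retained (",
      nrow(object@removed), "removed )\n")
})

#' @rdname essMiner-accessors
setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
    object@tp, object@fp, object@fn, object@precision, object@recall,
    object@f1))
  if (nrow(object@slices))
    cat(sprintf("  %d slices: mean F1=%.4f, best F1=%.4f\n",
                nrow(object@slices), object@mean_f1, object@best_f1))
})
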