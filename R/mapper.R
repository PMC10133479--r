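# Mapping mined gene symbols onto the target genome, deduplication of the
# mapped list, pathway categorization and GO-term tabulation.

#' Map mined symbols onto the target genome
#'
#' A symbol maps iff its normalized surface form is in the dictionary lookup;
#' unmapped symbols (the stand-in for symbols with no homolog in the target
#' genus) are kept verbatim.  Every input line yields one mapped entry or one
#' unmapped entry, so repeated symbols produce repeated mapped entries —
#' those are collapsed later by [deduplicateMapped()].
#'
#' @param symbols character vector of mined gene symbols.
#' @param dictionary a [GeneDictionary-class].
#' @return A [MappingFunnel-class] with \code{mapped}/\code{unmapped}
#'   populated and empty \code{removed}/\code{retained}.
#' @examples
#' d <- loadFixtures()$dictionary
#' f <- mapToGenome(c("dsrA", "nosuchgene"), d)
#' mappedGenes(f)$locus_tag
#' @export
mapToGenome <- function(symbols, dictionary) {
  stopifnot(is(dictionary, "GeneDictionary"))
  symbols <- as.character(symbols)
  lookup <- surfaceLookup(dictionary)
  rec <- geneRecords(dictionary)
  hit <- lookup[normSurface(symbols)]
  ok <- !is.na(hit)
  idx <- match(hit[ok], rec$locus_tag)
  mapped <- data.frame(symbol = symbols[ok], locus_tag = unname(hit[ok]),
                       product = rec$product[idx], pathway = rec$pathway[idx],
                       stringsAsFactors = FALSE)
  new("MappingFunnel", input = symbols, mapped = mapped,
      unmapped = symbols[!ok], removed = emptyMapped(reason = TRUE),
      retained = emptyMapped())
}

emptyMapped <- function(reason = FALSE) {
  d <- data.frame(symbol = character(), locus_tag = character(),
                  product = character(), pathway = character(),
                  stringsAsFactors = FALSE)
  if (reason) d$reason <- character()
  d
}

#' Collapse duplicate entries in a mapped gene list
#'
#' Two kinds of redundancy are collapsed, keeping the first occurrence as the
#' representative:
#' \itemize{
#'   \item \emph{duplicate-locus}: entries resolving to the same locus tag
#'     (the same gene mined under different names);
#'   \item \emph{duplicate-product}: entries with the same normalized product
#'     name \emph{and} the same symbol family \emph{and} compatible subunit
#'     qualifiers (equal, or one side has none) — same-name paralogs and
#'     bare-family re-mentions.
#' }
#' Product equality alone deliberately never merges: curated annotation
#' tables routinely print the identical product string for distinct genes
#' (different subunits or isozymes), so entries that differ in both locus tag
#' and symbol spelling beyond the subunit letter are kept.  This is the
#' module's riskiest rule; see the package vignette for the rationale.
#'
#' @param funnel a [MappingFunnel-class] with \code{mapped} populated, or a
#'   \code{data.frame} shaped like its \code{mapped} slot.
#' @return The funnel with \code{removed} (with a \code{reason} column) and
#'   \code{retained} populated.  Idempotent: deduplicating the retained set
#'   removes nothing.
#' @export
deduplicateMapped <- function(funnel) {
  if (is.data.frame(funnel)) {
    funnel <- new("MappingFunnel", input = funnel$symbol, mapped = funnel,
                  unmapped = character(), removed = emptyMapped(reason = TRUE),
                  retained = emptyMapped())
  }
  stopifnot(is(funnel, "MappingFunnel"))
  m <- mappedGenes(funnel)
  if (!nrow(m)) {
    funnel@retained <- emptyMapped()
    funnel@removed <- emptyMapped(reason = TRUE)
    return(funnel)
  }
  keep <- logical(nrow(m))
  reason <- character(nrow(m))
  fam <- symbolFamily(m$symbol)
  qual <- symbolQualifier(m$symbol)
  prod <- normProduct(m$product)
  seen_locus <- character()
  kept_idx <- integer()
  for (i in seq_len(nrow(m))) {
    if (m$locus_tag[i] %in% seen_locus) {
      reason[i] <- "duplicate-locus"
      next
    }
    prod_dup <- FALSE
    for (j in kept_idx) {
      if (prod[i] == prod[j] && nzchar(prod[i]) && fam[i] == fam[j] &&
          (qual[i] == qual[j] || !nzchar(qual[i]) || !nzchar(qual[j]))) {
        prod_dup <- TRUE
        break
      }
    }
    if (prod_dup) {
      reason[i] <- "duplicate-product"
    } else {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
    seen_locus <- c(seen_locus, m$locus_tag[i])
  }
  removed <- m[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  retained <- m[keep, , drop = FALSE]
  rownames(retained) <- NULL
  funnel@removed <- removed
  funnel@retained <- retained
  validObject(funnel)
  funnel
}

#' Partition retained genes by pathway
#'
#' @param retained \code{data.frame} with at least \code{locus_tag} (or
#'   \code{gene}) and \code{pathway} columns; records lacking a pathway are
#'   flagged \code{"uncategorized"}, never dropped.
#' @return A list with \code{genes} (named list pathway -> gene vector) and
#'   \code{census} (named integer, sums to the number of input genes).
#' @examples
#' fx <- loadFixtures()
#' categorizePathways(geneRecords(fx$dictionary))$census
#' @export
categorizePathways <- function(retained) {
  retained <- as.data.frame(retained, stringsAsFactors = FALSE)
  id_col <- if ("locus_tag" %in% names(retained)) "locus_tag" else "gene"
  if (!nrow(retained))
    return(list(genes = list(), census = integer()))
  pw <- retained$pathway
  if (is.null(pw)) pw <- rep(NA_character_, nrow(retained))
  pw[is.na(pw) | !nzchar(trimws(pw))] <- "uncategorized"
  lev <- c(intersect(pathwayLevels(), pw), setdiff(unique(pw), pathwayLevels()))
  genes <- split(retained[[id_col]], factor(pw, levels = lev))
  list(genes = genes, census = vapply(genes, length, integer(1)))
}

#' Tabulate GO-term frequencies by aspect
#'
#' Counts, for every GO term, how many genes carry it, split by GO aspect
#' (molecular function \code{F}, biological process \code{P}, cellular
#' component \code{C}).  A gene with k GO terms contributes to exactly k
#' cells.  Also reports the top term per aspect.
#'
#' @param genes \code{data.frame} with \code{locus_tag} and \code{go_terms}
#'   columns (the [geneRecords()] dialect).
#' @return A list with \code{table} (\code{data.frame} of \code{aspect},
#'   \code{go_id}, \code{count}) and \code{top} (\code{data.frame} of the
#'   highest-count term per aspect).
#' @export
goTermFrequency <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  empty <- list(table = data.frame(aspect = character(), go_id = character(),
                                   count = integer()),
                top = data.frame(aspect = character(), go_id = character(),
                                 count = integer()))
  if (!nrow(genes)) return(empty)
  parsed <- parseGoTerms(genes$go_terms)
  rows <- do.call(rbind, lapply(seq_along(parsed), function(i) {
    p <- unique(parsed[[i]])
    if (!nrow(p)) return(NULL)
    cbind(locus_tag = genes$locus_tag[i], p)
  }))
  if (is.null(rows)) return(empty)
  bad <- !rows$aspect %in% c("F", "P", "C")
  if (any(bad))
    stop("unknown GO aspect for ", paste(unique(rows$locus_tag[bad]),
                                         collapse = ", "), call. = FALSE)
  agg <- aggregate(list(count = rows$locus_tag),
                   by = list(aspect = rows$aspect, go_id = rows$go_id),
                   FUN = length)
  agg <- agg[order(agg$aspect, -agg$count, agg$go_id), ]
  rownames(agg) <- NULL
  top <- do.call(rbind, lapply(split(agg, agg$aspect), function(d) d[1L, ]))
  rownames(top) <- NULL
  list(table = agg, top = top)
}

#' @importFrom stats aggregate
NULL
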