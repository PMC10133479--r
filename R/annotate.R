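# Dictionary-based gene mention tagging ("Microbe annotator" /
# "Microbe recognizer" stages) with granularization of long texts.

tokenBoundaryOk <- function(text_lc, start1, end1) {
  # start1/end1 are 1-based inclusive; a hit is token-bounded when the
  # characters flanking it are not word characters (letters/digits/underscore)
  before <- ifelse(start1 == 1L, "",
                   substr(text_lc, start1 - 1L, start1 - 1L))
  after <- substr(text_lc, end1 + 1L, end1 + 1L)
  !grepl("[A-Za-z0-9_]", before) & !grepl("[A-Za-z0-9_]", after)
}

## All dictionary hits in `text`, unresolved (may overlap).
candidateMentions <- function(text, dictionary) {
  lookup <- surfaceLookup(dictionary)
  if (!length(lookup) || !nzchar(text))
    return(data.frame(start = integer(), end = integer(), text = character(),
                      locus_tag = character(), stringsAsFactors = FALSE))
  text_lc <- tolower(text)
  hits <- lapply(seq_along(lookup), function(i) {
    surf <- names(lookup)[i]
    m <- gregexpr(surf, text_lc, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start1 <- as.integer(m)
    end1 <- start1 + nchar(surf) - 1L
    keep <- tokenBoundaryOk(text_lc, start1, end1)
    if (!any(keep)) return(NULL)
    data.frame(start = start1[keep] - 1L, end = end1[keep],
               locus_tag = lookup[[i]], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(start = integer(), end = integer(), text = character(),
                      locus_tag = character(), stringsAsFactors = FALSE))
  hits$text <- substr(rep(text, nrow(hits)), hits$start + 1L, hits$end)
  hits[, c("start", "end", "text", "locus_tag")]
}

## Longest-match-first, then leftmost, greedy non-overlapping selection.
resolveOverlaps <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  kept <- logical(nrow(cand))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!nrow(occupied) || all(e <= occupied[, 1] | s >= occupied[, 2])) {
      kept[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Split a long text into overlapping segments
#'
#' Long documents are split into windows of \code{window} characters which
#' consecutively overlap by \code{overlap} characters, so that a mention
#' spanning a window edge is fully contained in at least one segment (choose
#' \code{overlap} at least the longest surface form minus one).  Segment-local
#' offsets map back to global coordinates by adding the segment's
#' \code{offset}.
#'
#' @param text character scalar.
#' @param window segment length in characters (> 0).
#' @param overlap overlap between consecutive segments, \code{0 <= overlap <
#'   window}.
#' @return \code{data.frame} with columns \code{text}, \code{offset}
#'   (0-based global offset of the segment start); zero rows for empty text.
#' @examples
#' granularize(strrep("x", 1000), window = 400, overlap = 100)$offset
#' @export
granularize <- function(text, window, overlap = 0L) {
  stopIfNot(length(text) == 1L, "text must be a single string")
  stopIfNot(window >= 1, "window must be positive")
  stopIfNot(overlap >= 0 && overlap < window,
            "overlap must satisfy 0 <= overlap < window")
  n <- nchar(text)
  if (n == 0L) return(data.frame(text = character(), offset = integer()))
  if (n <= window) return(data.frame(text = text, offset = 0L))
  step <- window - overlap
  starts <- as.integer(step * (0:ceiling((n - window) / step)))
  data.frame(text = substr(rep(text, length(starts)), starts + 1L,
                           pmin(starts + window, n)),
             offset = starts, stringsAsFactors = FALSE)
}

#' Annotate one document with dictionary gene mentions
#'
#' Deterministic dictionary tagging: every surface form of the dictionary is
#' matched case-insensitively at token boundaries (transitions between word
#' characters and non-word characters, so \code{dde_2265} tokenizes intact
#' and \code{sat} inside \code{sulfate} is not a hit); overlapping candidate
#' matches are resolved longest-first, then leftmost.  When \code{window} is
#' given the text is first [granularize()]d, each segment is tagged, and the
#' segment mentions are reconciled to global offsets and deduplicated —
#' equivalent to whole-text tagging.
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param dictionary a [GeneDictionary-class].
#' @param window,overlap optional granularization parameters.
#' @return An [AnnotatedCorpus-class] with a single document.
#' @examples
#' d <- loadFixtures()$dictionary
#' mentions(annotateDocument("d1", "The dsrA and sat genes", d))
#' @export
annotateDocument <- function(doc_id, text, dictionary, window = NULL,
                             overlap = 0L) {
  stopifnot(is(dictionary, "GeneDictionary"))
  if (is.null(window)) {
    men <- resolveOverlaps(candidateMentions(text, dictionary))
  } else {
    segs <- granularize(text, window, overlap)
    cand <- do.call(rbind, c(list(
      data.frame(start = integer(), end = integer(), text = character(),
                 locus_tag = character(), stringsAsFactors = FALSE)),
      lapply(seq_len(nrow(segs)), function(i) {
        m <- candidateMentions(segs$text[i], dictionary)
        m$start <- m$start + segs$offset[i]
        m$end <- m$end + segs$offset[i]
        m
      })))
    cand <- cand[!duplicated(cand[, c("start", "end", "locus_tag")]), ,
                 drop = FALSE]
    men <- resolveOverlaps(cand)
  }
  men <- cbind(doc_id = rep(doc_id, nrow(men)), men)
  rownames(men) <- NULL
  new("AnnotatedCorpus",
      documents = data.frame(doc_id = doc_id, text = text,
                             stringsAsFactors = FALSE),
      mentions = men)
}

#' Annotate a whole corpus
#'
#' Applies [annotateDocument()] to every document; existing (gold)
#' annotations are discarded in the output, which carries the dictionary
#' predictions.  Tagging is per-document and therefore independent of
#' document order.
#'
#' @param corpus an [AnnotatedCorpus-class] (its texts are used).
#' @param dictionary a [GeneDictionary-class].
#' @inheritParams annotateDocument
#' @return An [AnnotatedCorpus-class] with predicted mentions.
#' @export
annotateCorpus <- function(corpus, dictionary, window = NULL, overlap = 0L) {
  stopifnot(is(corpus, "AnnotatedCorpus"))
  doc <- documents(corpus)
  men <- do.call(rbind, c(list(emptyMentions()),
    lapply(seq_len(nrow(doc)), function(i)
      mentions(annotateDocument(doc$doc_id[i], doc$text[i], dictionary,
                                window, overlap)))))
  new("AnnotatedCorpus", documents = doc, mentions = men)
}

emptyMentions <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             text = character(), locus_tag = character(),
             stringsAsFactors = FALSE)
}

#' Per-document recognized gene lists and the corpus funnel
#'
#' Deduplicates each document's mentions to the set of distinct locus tags,
#' and reports the corpus-level funnel: total mentions with duplicates versus
#' distinct genes recognized (the mined-mentions-to-unique-genes reduction).
#'
#' @param corpus an [AnnotatedCorpus-class] with mentions (gold or
#'   predicted).
#' @return A list with \code{per_document} (named list of locus-tag character
#'   vectors), \code{total_mentions}, \code{unique_genes}.
#' @export
recognizeGenes <- function(corpus) {
  stopifnot(is(corpus, "AnnotatedCorpus"))
  doc <- documents(corpus)
  men <- mentions(corpus)
  per_doc <- lapply(setNames(doc$doc_id, doc$doc_id), function(d)
    sort(unique(men$locus_tag[men$doc_id == d])))
  list(per_document = per_doc,
       total_mentions = nrow(men),
       unique_genes = length(unique(men$locus_tag)))
}

#' Read / write the JSONL corpus dialect
#'
#' One JSON object per line:
#' \code{\{"doc_id": ..., "text": ..., "annotations": [\{"start": ...,
#' "end": ..., "text": ..., "locus_tag": ...\}]\}}.  Offsets are 0-based
#' half-open character positions.
#'
#' @param path file path.
#' @param corpus an [AnnotatedCorpus-class].
#' @return \code{readCorpusJsonl} returns an [AnnotatedCorpus-class];
#'   \code{writeCorpusJsonl} returns \code{path} invisibly.
#' @export
readCorpusJsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- list(); mens <- list()
  for (ln in lines) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    docs[[length(docs) + 1L]] <- data.frame(doc_id = o$doc_id, text = o$text,
                                            stringsAsFactors = FALSE)
    a <- o$annotations
    if (!is.null(a) && length(a) && NROW(a) > 0) {
      a <- as.data.frame(a, stringsAsFactors = FALSE)
      mens[[length(mens) + 1L]] <- data.frame(
        doc_id = o$doc_id, start = as.integer(a$start),
        end = as.integer(a$end), text = a$text, locus_tag = a$locus_tag,
        stringsAsFactors = FALSE)
    }
  }
  new("AnnotatedCorpus",
      documents = do.call(rbind, c(list(data.frame(doc_id = character(),
                                                   text = character())), docs)),
      mentions = do.call(rbind, c(list(emptyMentions()), mens)))
}

#' @rdname readCorpusJsonl
#' @export
writeCorpusJsonl <- function(corpus, path) {
  stopifnot(is(corpus, "AnnotatedCorpus"))
  doc <- documents(corpus)
  men <- mentions(corpus)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(doc))) {
    a <- men[men$doc_id == doc$doc_id[i], c("start", "end", "text", "locus_tag")]
    rownames(a) <- NULL
    obj <- list(doc_id = doc$doc_id[i], text = doc$text[i], annotations = a)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows",
                                digits = NA), con)
  }
  invisible(path)
}
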